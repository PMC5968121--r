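#' @include AllClasses.R
NULL

#' Default per-feature-class regularisation table
#'
#' The per-class base penalties interpolated by presence sample size that
#' the published maxent formulation applies before the user's
#' regularisation multiplier. Each entry maps sample-size breakpoints to
#' base penalties (linear interpolation, clamped at the ends). The table
#' is an ordinary list — edit it and pass the result to [fitConfig()] to
#' change the defaults.
#'
#' @return named list: per class, a list with numeric `n` and `beta`.
#' @export
regularizationDefaults <- function() {
  list(
    L = list(n = c(0, 10, 30, 100), beta = c(1, 1, 0.2, 0.05)),
    Q = list(n = c(0, 10, 30, 100), beta = c(1, 1, 0.2, 0.05)),
    P = list(n = c(0, 10, 17, 30, 100), beta = c(2.6, 2.6, 2, 1, 0.05)),
    T = list(n = c(0, 100), beta = c(2, 1)),
    H = list(n = c(0, 100), beta = c(0.5, 0.5)),
    C = list(n = c(0, 10, 17), beta = c(0.65, 0.5, 0.25))
  )
}

.classDefaultBeta <- function(kind, n, table) {
  vapply(kind, function(k) {
    e <- table[[k]]
    if (is.null(e)) stop(sprintf("no regularisation defaults for class '%s'", k))
    stats::approx(e$n, e$beta, xout = n, rule = 2)$y
  }, numeric(1))
}

#' Fit settings for the maximum-entropy model
#'
#' @param tolerance convergence threshold on the change in regularised
#'   gain per update (default 1e-6).
#' @param maxIter maximum number of coordinate updates (default 5000).
#' @param betaTable per-class base-penalty table
#'   (default [regularizationDefaults()]).
#' @param minSd floor on the presence-sample feature standard deviation
#'   entering the penalty scaling.
#' @return list of class `fitConfig`.
#' @export
fitConfig <- function(tolerance = 1e-6, maxIter = 5000,
                      betaTable = regularizationDefaults(), minSd = 1e-4) {
  stopifnot(tolerance > 0, maxIter >= 1)
  structure(list(tolerance = tolerance, maxIter = as.integer(maxIter),
                 betaTable = betaTable, minSd = minSd),
            class = "fitConfig")
}

#' Fit an L1-regularised maximum-entropy habitat model
#'
#' Maximises the penalised log-likelihood
#' \deqn{\sum_{presence} \log q_\lambda(x) - \sum_j \beta_j |\lambda_j|,
#'   \quad q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z}}
#' with `Z` summed over the background, by greedy coordinate-wise ascent:
#' each update picks the feature with the largest penalised directional
#' gradient (ties to the lowest feature index), takes a soft-thresholded
#' Newton step, and backtracks until the objective does not decrease.
#' Per-feature penalties are
#' `beta_j = regMultiplier * classDefault(kind_j, n) * sd_j / sqrt(n)`
#' with `sd_j` the presence-sample standard deviation of feature `j` and
#' `n` the presence count. Iteration stops when the gain improves by less
#' than the tolerance or the iteration cap is reached (the model is then
#' returned with `isConverged(model) == FALSE`).
#'
#' The recorded "gain" trajectory is the regularised training gain (mean
#' presence log-probability minus the log-uniform baseline, minus the L1
#' penalty), which is non-decreasing by construction; per-update gain
#' changes are credited to the updated feature and back percent
#' contribution.
#'
#' @param presence,background [FeatureMatrix-class] objects built with the
#'   same definitions (the background expansion is the usual reference).
#' @param regMultiplier global regularisation multiplier (>= 0).
#' @param config a [fitConfig()].
#' @return a [MaxentModel-class].
#' @export
fitMaxent <- function(presence, background, regMultiplier = 1,
                      config = fitConfig()) {
  stopifnot(is(presence, "FeatureMatrix"), is(background, "FeatureMatrix"),
            regMultiplier >= 0)
  if (!identical(presence@defs$name, background@defs$name))
    stop("presence and background were expanded with different feature definitions")
  Mp <- presence@M; Mb <- background@M
  if (nrow(Mp) < 1 || nrow(Mb) < 2)
    stop("need at least 1 presence and 2 background rows")
  if (any(!is.finite(Mp)) || any(!is.finite(Mb)))
    stop("non-finite feature values")
  n <- nrow(Mp); nb <- nrow(Mb); nf <- ncol(Mb)
  a <- colMeans(Mp)
  sdj <- pmax(apply(Mp, 2, stats::sd), config$minSd)
  if (n == 1) sdj <- rep(config$minSd, nf)
  beta <- regMultiplier *
    .classDefaultBeta(background@defs$kind, n, config$betaTable) *
    sdj / sqrt(n)

  lambda <- numeric(nf)
  eta <- numeric(nb)
  logZ <- log(nb)
  obj <- -log(nb)                       # a.lambda - logZ - penalty at lambda = 0
  credits <- numeric(nf)
  traj <- numeric(config$maxIter)
  converged <- FALSE
  iter <- 0L

  q <- rep(1 / nb, nb)
  repeat {
    if (iter >= config$maxIter) break
    Ef <- as.vector(crossprod(Mb, q))
    grad <- a - Ef
    eff <- numeric(nf)
    pos <- lambda > 0 | (lambda == 0 & grad > beta)
    neg <- lambda < 0 | (lambda == 0 & grad < -beta)
    eff[pos] <- grad[pos] - beta[pos]
    eff[neg] <- grad[neg] + beta[neg]
    j <- which.max(abs(eff))            # ties -> lowest index
    fj <- Mb[, j]
    h <- max(sum(q * fj * fj) - Ef[j]^2, 1e-12)
    u <- h * lambda[j] + grad[j]
    lnew <- sign(u) * max(abs(u) - beta[j], 0) / h
    delta <- lnew - lambda[j]
    if (delta > 10) delta <- 10 else if (delta < -10) delta <- -10
    if (delta == 0) { converged <- TRUE; break }

    accepted <- FALSE
    for (bt in 1:40) {
      cand <- lambda[j] + delta
      etaNew <- eta + delta * fj
      logZNew <- .logSumExp(etaNew)
      objNew <- sum(a * lambda) + a[j] * delta - logZNew -
        sum(beta * abs(lambda)) - beta[j] * (abs(cand) - abs(lambda[j]))
      if (objNew >= obj - 1e-14) { accepted <- TRUE; break }
      delta <- delta / 2
    }
    if (!accepted || objNew - obj < 0) { converged <- TRUE; break }
    improvement <- objNew - obj
    lambda[j] <- lambda[j] + delta
    eta <- etaNew; logZ <- logZNew
    q <- exp(eta - logZ)
    credits[j] <- credits[j] + improvement
    obj <- objNew
    iter <- iter + 1L
    traj[iter] <- obj + log(nb)
    if (improvement < config$tolerance) { converged <- TRUE; break }
  }

  gain <- sum(a * lambda) - logZ + log(nb)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  names(lambda) <- names(beta) <- names(credits) <- background@defs$name
  new("MaxentModel", lambda = lambda, beta = beta, logZ = logZ, H = H,
      gain = gain, regGain = obj + log(nb),
      gainTrajectory = traj[seq_len(iter)], gainCredits = credits,
      defs = background@defs, varSummary = background@varSummary,
      classes = background@classes, converged = converged,
      iterations = as.numeric(iter), regMultiplier = regMultiplier,
      config = unclass(config)[c("tolerance", "maxIter", "minSd")],
      nPresence = as.numeric(n), nBackground = as.numeric(nb))
}

# Penalised objective of a weight vector on given feature matrices --
# shared by fitMaxent tests and the model-selection oracle.
#' Penalised maxent objective for explicit weights
#'
#' Mean presence score minus the log background normaliser minus the L1
#' penalty — the quantity [fitMaxent()] maximises. Exposed so that
#' alternative optimisers can be compared against the fitted model.
#'
#' @param lambda numeric weight vector.
#' @param presence,background [FeatureMatrix-class] objects (or bare
#'   matrices).
#' @param beta per-feature penalty vector.
#' @return the objective value.
#' @export
maxentObjective <- function(lambda, presence, background, beta) {
  Mp <- if (is(presence, "FeatureMatrix")) presence@M else presence
  Mb <- if (is(background, "FeatureMatrix")) background@M else background
  sum(colMeans(Mp) * lambda) - .logSumExp(as.vector(Mb %*% lambda)) -
    sum(beta * abs(lambda))
}
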