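#' @include AllClasses.R
NULL

# Run expr under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL uses the current stream (caller-managed reproducibility).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Integerise a nonnegative vector to a given total by largest remainders.
# Conserves the total exactly; ties broken by earlier index.
.largestRemainder <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0)
  if (sum(x) == 0) return(integer(length(x)))
  target <- x / sum(x) * total
  fl <- floor(target)
  left <- as.integer(round(total - sum(fl)))
  if (left > 0) {
    ord <- order(-(target - fl), seq_along(x))
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  as.integer(fl)
}

.isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
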