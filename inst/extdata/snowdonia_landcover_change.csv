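class_id,name,area_2015_km2,area_2050_km2,printed_change_pct
1,Cropland,0.5586,0.5586,0
2,Herbaceous cover,3.72,4.9,28.7
3,Mosaic cropland,8.19,8.19,0
4,Mosaic natural vegetation,6.08,6.08,0
5,Broadleaved Deciduous Trees,19.61,12.53,-36.1
6,Needleleaved Evergreen Trees,229.64,223.62,-2.62
7,Needleleaved Deciduous Trees,0.3724,0.3724,0
8,Mosaic tree and shrub,141.44,147.84,4.52
9,Mosaic herbaceous cover,627.55,637.98,1.66
10,Grassland,930.37,925.28,-0.54
11,Sparse vegetation,85.15,85.15,0
12,Shrub or herbaceous cover,25.75,25.94,0.73
13,Urban areas,2.85,2.85,0
14,Bare areas,10.42,10.42,0
15,Unconsolidated bare areas,1.55,1.55,0
16,Water bodies,32.27,32.27,0
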