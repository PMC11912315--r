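"year","delta_T_C","co2_ratio","label"
2025,"0.042000000000000003","            1.0037","rcp85_like_warming_synthetic"
2026,"0.084000000000000005","1.0074000000000001","rcp85_like_warming_synthetic"
2027,"             0.126","1.0111000000000001","rcp85_like_warming_synthetic"
2028,"0.16800000000000001","1.0147999999999999","rcp85_like_warming_synthetic"
2029,"0.21000000000000002","            1.0185","rcp85_like_warming_synthetic"
2030,"             0.252","            1.0222","rcp85_like_warming_synthetic"
2031,"0.29400000000000004","            1.0259","rcp85_like_warming_synthetic"
2032,"0.33600000000000002","1.0296000000000001","rcp85_like_warming_synthetic"
2033,"             0.378","1.0333000000000001","rcp85_like_warming_synthetic"
2034,"0.42000000000000004","1.0369999999999999","rcp85_like_warming_synthetic"
2035,"0.46200000000000002","            1.0407","rcp85_like_warming_synthetic"
2036,"             0.504","            1.0444","rcp85_like_warming_synthetic"
2037,"0.54600000000000004","            1.0481","rcp85_like_warming_synthetic"
2038,"0.58800000000000008","1.0518000000000001","rcp85_like_warming_synthetic"
2039,"              0.63","1.0555000000000001","rcp85_like_warming_synthetic"
2040,"0.67200000000000004","1.0591999999999999","rcp85_like_warming_synthetic"
2041,"0.71400000000000008","            1.0629","rcp85_like_warming_synthetic"
2042,"0.75600000000000001","            1.0666","rcp85_like_warming_synthetic"
2043,"0.79800000000000004","            1.0703","rcp85_like_warming_synthetic"
2044,"0.84000000000000008","1.0740000000000001","rcp85_like_warming_synthetic"
2045,"0.88200000000000001","1.0777000000000001","rcp85_like_warming_synthetic"
2046,"0.92400000000000004","1.0813999999999999","rcp85_like_warming_synthetic"
2047,"0.96600000000000008","            1.0851","rcp85_like_warming_synthetic"
2048,"             1.008","            1.0888","rcp85_like_warming_synthetic"
2049,"              1.05","            1.0925","rcp85_like_warming_synthetic"
2050,"1.0920000000000001","1.0962000000000001","rcp85_like_warming_synthetic"
2051,"1.1340000000000001","1.0999000000000001","rcp85_like_warming_synthetic"
2052,"1.1760000000000002","1.1035999999999999","rcp85_like_warming_synthetic"
2053,"             1.218","            1.1073","rcp85_like_warming_synthetic"
2054,"              1.26","             1.111","rcp85_like_warming_synthetic"
2055,"             1.302","            1.1147","rcp85_like_warming_synthetic"
2056,"1.3440000000000001","1.1184000000000001","rcp85_like_warming_synthetic"
2057,"1.3860000000000001","1.1221000000000001","rcp85_like_warming_synthetic"
2058,"1.4280000000000002","1.1257999999999999","rcp85_like_warming_synthetic"
2059,"1.4700000000000002","1.1294999999999999","rcp85_like_warming_synthetic"
2060,"             1.512","            1.1332","rcp85_like_warming_synthetic"
2061,"             1.554","            1.1369","rcp85_like_warming_synthetic"
2062,"1.5960000000000001","1.1406000000000001","rcp85_like_warming_synthetic"
2063,"1.6380000000000001","1.1443000000000001","rcp85_like_warming_synthetic"
2064,"1.6800000000000002","1.1480000000000001","rcp85_like_warming_synthetic"
2065,"1.7220000000000002","1.1516999999999999","rcp85_like_warming_synthetic"
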