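"year","delta_T_C","co2_ratio","label"
2025,"0.033000000000000002","             1.002","carbon_neutral_2045_synthetic"
2026,"0.066000000000000003","             1.004","carbon_neutral_2045_synthetic"
2027,"0.099000000000000005","             1.006","carbon_neutral_2045_synthetic"
2028,"0.13200000000000001","             1.008","carbon_neutral_2045_synthetic"
2029,"0.16500000000000001","              1.01","carbon_neutral_2045_synthetic"
2030,"0.19800000000000001","             1.012","carbon_neutral_2045_synthetic"
2031,"0.23100000000000001","             1.014","carbon_neutral_2045_synthetic"
2032,"0.26400000000000001","             1.016","carbon_neutral_2045_synthetic"
2033,"0.29700000000000004","             1.018","carbon_neutral_2045_synthetic"
2034,"0.33000000000000002","              1.02","carbon_neutral_2045_synthetic"
2035,"0.36299999999999999","             1.022","carbon_neutral_2045_synthetic"
2036,"0.39600000000000002","             1.024","carbon_neutral_2045_synthetic"
2037,"0.42900000000000005","             1.026","carbon_neutral_2045_synthetic"
2038,"0.46200000000000002","             1.028","carbon_neutral_2045_synthetic"
2039,"             0.495","              1.03","carbon_neutral_2045_synthetic"
2040,"0.52800000000000002","             1.032","carbon_neutral_2045_synthetic"
2041,"0.56100000000000005","             1.034","carbon_neutral_2045_synthetic"
2042,"0.59400000000000008","             1.036","carbon_neutral_2045_synthetic"
2043,"             0.627","             1.038","carbon_neutral_2045_synthetic"
2044,"0.66000000000000003","              1.04","carbon_neutral_2045_synthetic"
2045,"0.69300000000000006","             1.042","carbon_neutral_2045_synthetic"
2046,"0.72599999999999998","             1.042","carbon_neutral_2045_synthetic"
2047,"0.75900000000000001","             1.042","carbon_neutral_2045_synthetic"
2048,"0.79200000000000004","             1.042","carbon_neutral_2045_synthetic"
2049,"0.82500000000000007","             1.042","carbon_neutral_2045_synthetic"
2050,"0.8580000000000001","             1.042","carbon_neutral_2045_synthetic"
2051,"0.89100000000000001","             1.042","carbon_neutral_2045_synthetic"
2052,"0.92400000000000004","             1.042","carbon_neutral_2045_synthetic"
2053,"0.95700000000000007","             1.042","carbon_neutral_2045_synthetic"
2054,"0.98999999999999999","             1.042","carbon_neutral_2045_synthetic"
2055,"1.0230000000000001","             1.042","carbon_neutral_2045_synthetic"
2056,"             1.056","             1.042","carbon_neutral_2045_synthetic"
2057,"             1.089","             1.042","carbon_neutral_2045_synthetic"
2058,"1.1220000000000001","             1.042","carbon_neutral_2045_synthetic"
2059,"             1.155","             1.042","carbon_neutral_2045_synthetic"
2060,"1.1880000000000002","             1.042","carbon_neutral_2045_synthetic"
2061,"1.2210000000000001","             1.042","carbon_neutral_2045_synthetic"
2062,"             1.254","             1.042","carbon_neutral_2045_synthetic"
2063,"1.2870000000000001","             1.042","carbon_neutral_2045_synthetic"
2064,"1.3200000000000001","             1.042","carbon_neutral_2045_synthetic"
2065,"             1.353","             1.042","carbon_neutral_2045_synthetic"
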