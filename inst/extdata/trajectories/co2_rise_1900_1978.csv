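"year","delta_T_C","co2_ratio","label"
1900,"-0.39000000000000001","0.35714285714285715","co2_rise_1900_1978_synthetic"
1901,"-0.38500000000000001","0.36188848458655298","co2_rise_1900_1978_synthetic"
1902,"             -0.38","0.36669717077378511","co2_rise_1900_1978_synthetic"
1903,"            -0.375","0.37156975361380423","co2_rise_1900_1978_synthetic"
1904,"             -0.37","0.37650708214979584","co2_rise_1900_1978_synthetic"
1905,"-0.36499999999999999","0.38151001670682438","co2_rise_1900_1978_synthetic"
1906,"-0.35999999999999999","0.38657942904174497","co2_rise_1900_1978_synthetic"
1907,"-0.35499999999999998","0.39171620249510558","co2_rise_1900_1978_synthetic"
1908,"-0.35000000000000003","0.39692123214506864","co2_rise_1900_1978_synthetic"
1909,"-0.34500000000000003","0.40219542496337768","co2_rise_1900_1978_synthetic"
1910,"-0.34000000000000002","0.40753969997339601","co2_rise_1900_1978_synthetic"
1911,"-0.33500000000000002","0.41295498841024614","co2_rise_1900_1978_synthetic"
1912,"-0.33000000000000002","0.41844223388307633","co2_rise_1900_1978_synthetic"
1913,"-0.32500000000000001","0.42400239253948369","co2_rise_1900_1978_synthetic"
1914,"-0.32000000000000001","0.42963643323212236","co2_rise_1900_1978_synthetic"
1915,"            -0.315","0.43534533768752465","co2_rise_1900_1978_synthetic"
1916,"             -0.31","0.44113010067716657","co2_rise_1900_1978_synthetic"
1917,"-0.30499999999999999","0.4469917301908054","co2_rise_1900_1978_synthetic"
1918,"-0.29999999999999999","0.45293124761212145","co2_rise_1900_1978_synthetic"
1919,"-0.29499999999999998","0.45894968789669283","co2_rise_1900_1978_synthetic"
1920,"-0.28999999999999998","0.4650480997523358","co2_rise_1900_1978_synthetic"
1921,"-0.28500000000000003","0.47122754582184107","co2_rise_1900_1978_synthetic"
1922,"-0.28000000000000003","0.47748910286813823","co2_rise_1900_1978_synthetic"
1923,"-0.27500000000000002","0.48383386196192113","co2_rise_1900_1978_synthetic"
1924,"-0.27000000000000002","0.49026292867176557","co2_rise_1900_1978_synthetic"
1925,"-0.26500000000000001","0.4967774232567736","co2_rise_1900_1978_synthetic"
1926,"-0.26000000000000001","0.50337848086177805","co2_rise_1900_1978_synthetic"
1927,"            -0.255","  0.51006725171514","co2_rise_1900_1978_synthetic"
1928,"             -0.25","0.51684490132917571","co2_rise_1900_1978_synthetic"
1929,"            -0.245","0.52371261070324537","co2_rise_1900_1978_synthetic"
1930,"-0.23999999999999999","0.53067157652954156","co2_rise_1900_1978_synthetic"
1931,"-0.23500000000000001","0.53772301140161194","co2_rise_1900_1978_synthetic"
1932,"-0.23000000000000001","0.54486814402565187","co2_rise_1900_1978_synthetic"
1933,"-0.22500000000000001","0.55210821943460642","co2_rise_1900_1978_synthetic"
1934,"             -0.22","0.55944449920511541","co2_rise_1900_1978_synthetic"
1935,"            -0.215","0.56687826167734234","co2_rise_1900_1978_synthetic"
1936,"-0.20999999999999999","0.57441080217772411","co2_rise_1900_1978_synthetic"
1937,"-0.20500000000000002","0.58204343324467989","co2_rise_1900_1978_synthetic"
1938,"-0.20000000000000001","0.58977748485732095","co2_rise_1900_1978_synthetic"
1939,"-0.19500000000000001","0.59761430466719678","co2_rise_1900_1978_synthetic"
1940,"             -0.19","0.60555525823312373","co2_rise_1900_1978_synthetic"
1941,"            -0.185","0.61360172925913092","co2_rise_1900_1978_synthetic"
1942,"-0.17999999999999999","0.62175511983557075","co2_rise_1900_1978_synthetic"
1943,"-0.17500000000000002","0.63001685068343105","co2_rise_1900_1978_synthetic"
1944,"-0.17000000000000001","0.63838836140189459","co2_rise_1900_1978_synthetic"
1945,"-0.16500000000000001","0.64687111071918824","co2_rise_1900_1978_synthetic"
1946,"             -0.16","0.65546657674676467","co2_rise_1900_1978_synthetic"
1947,"            -0.155","0.66417625723686224","co2_rise_1900_1978_synthetic"
1948,"-0.14999999999999999","0.67300166984348664","co2_rise_1900_1978_synthetic"
1949,"-0.14499999999999999","0.68194435238686135","co2_rise_1900_1978_synthetic"
1950,"-0.14000000000000001","0.69100586312139078","co2_rise_1900_1978_synthetic"
1951,"-0.13500000000000001","0.70018778100718493","co2_rise_1900_1978_synthetic"
1952,"             -0.13","0.70949170598519196","co2_rise_1900_1978_synthetic"
1953,"            -0.125","0.7189192592559861","co2_rise_1900_1978_synthetic"
1954,"             -0.12","0.7284720835622609","co2_rise_1900_1978_synthetic"
1955,"            -0.115","0.73815184347507512","co2_rise_1900_1978_synthetic"
1956,"             -0.11","0.74796022568390319","co2_rise_1900_1978_synthetic"
1957,"            -0.105","0.75789893929053898","co2_rise_1900_1978_synthetic"
1958,"-0.10000000000000001","0.76796971610690545","co2_rise_1900_1978_synthetic"
1959,"-0.095000000000000001","0.77817431095682132","co2_rise_1900_1978_synthetic"
1960,"-0.089999999999999997","0.78851450198177764","co2_rise_1900_1978_synthetic"
1961,"-0.085000000000000006","0.79899209095077695","co2_rise_1900_1978_synthetic"
1962,"-0.080000000000000002","0.80960890357429038","co2_rise_1900_1978_synthetic"
1963,"-0.074999999999999997","0.82036678982238587","co2_rise_1900_1978_synthetic"
1964,"-0.070000000000000007","0.83126762424708378","co2_rise_1900_1978_synthetic"
1965,"-0.065000000000000002","0.84231330630899559","co2_rise_1900_1978_synthetic"
1966,"-0.059999999999999998","0.85350576070830408","co2_rise_1900_1978_synthetic"
1967,"            -0.055","0.86484693772013965","co2_rise_1900_1978_synthetic"
1968,"-0.050000000000000003","0.87633881353441456","co2_rise_1900_1978_synthetic"
1969,"-0.044999999999999998","0.88798339060017195","co2_rise_1900_1978_synthetic"
1970,"-0.040000000000000001","0.89978269797451116","co2_rise_1900_1978_synthetic"
1971,"-0.035000000000000003","0.91173879167614869","co2_rise_1900_1978_synthetic"
1972,"-0.029999999999999999","0.92385375504367795","co2_rise_1900_1978_synthetic"
1973,"-0.025000000000000001","0.9361296990985889","co2_rise_1900_1978_synthetic"
1974,"             -0.02","0.94856876291311176","co2_rise_1900_1978_synthetic"
1975,"-0.014999999999999999","0.96117311398294847","co2_rise_1900_1978_synthetic"
1976,"             -0.01","0.97394494860495673","co2_rise_1900_1978_synthetic"
1977,"-0.0050000000000000001","0.98688649225985292","co2_rise_1900_1978_synthetic"
1978,"                -0","                 1","co2_rise_1900_1978_synthetic"
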