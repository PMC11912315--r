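"year","delta_T_C","co2_ratio","label"
1800,"                 0","                 1","stable_1800s_synthetic"
1801,"                 0","                 1","stable_1800s_synthetic"
1802,"                 0","                 1","stable_1800s_synthetic"
1803,"                 0","                 1","stable_1800s_synthetic"
1804,"                 0","                 1","stable_1800s_synthetic"
1805,"                 0","                 1","stable_1800s_synthetic"
1806,"                 0","                 1","stable_1800s_synthetic"
1807,"                 0","                 1","stable_1800s_synthetic"
1808,"                 0","                 1","stable_1800s_synthetic"
1809,"                 0","                 1","stable_1800s_synthetic"
1810,"                 0","                 1","stable_1800s_synthetic"
1811,"                 0","                 1","stable_1800s_synthetic"
1812,"                 0","                 1","stable_1800s_synthetic"
1813,"                 0","                 1","stable_1800s_synthetic"
1814,"                 0","                 1","stable_1800s_synthetic"
1815,"                 0","                 1","stable_1800s_synthetic"
1816,"                 0","                 1","stable_1800s_synthetic"
1817,"                 0","                 1","stable_1800s_synthetic"
1818,"                 0","                 1","stable_1800s_synthetic"
1819,"                 0","                 1","stable_1800s_synthetic"
1820,"                 0","                 1","stable_1800s_synthetic"
1821,"                 0","                 1","stable_1800s_synthetic"
1822,"                 0","                 1","stable_1800s_synthetic"
1823,"                 0","                 1","stable_1800s_synthetic"
1824,"                 0","                 1","stable_1800s_synthetic"
1825,"                 0","                 1","stable_1800s_synthetic"
1826,"                 0","                 1","stable_1800s_synthetic"
1827,"                 0","                 1","stable_1800s_synthetic"
1828,"                 0","                 1","stable_1800s_synthetic"
1829,"                 0","                 1","stable_1800s_synthetic"
1830,"                 0","                 1","stable_1800s_synthetic"
1831,"                 0","                 1","stable_1800s_synthetic"
1832,"                 0","                 1","stable_1800s_synthetic"
1833,"                 0","                 1","stable_1800s_synthetic"
1834,"                 0","                 1","stable_1800s_synthetic"
1835,"                 0","                 1","stable_1800s_synthetic"
1836,"                 0","                 1","stable_1800s_synthetic"
1837,"                 0","                 1","stable_1800s_synthetic"
1838,"                 0","                 1","stable_1800s_synthetic"
1839,"                 0","                 1","stable_1800s_synthetic"
1840,"                 0","                 1","stable_1800s_synthetic"
1841,"                 0","                 1","stable_1800s_synthetic"
1842,"                 0","                 1","stable_1800s_synthetic"
1843,"                 0","                 1","stable_1800s_synthetic"
1844,"                 0","                 1","stable_1800s_synthetic"
1845,"                 0","                 1","stable_1800s_synthetic"
1846,"                 0","                 1","stable_1800s_synthetic"
1847,"                 0","                 1","stable_1800s_synthetic"
1848,"                 0","                 1","stable_1800s_synthetic"
1849,"                 0","                 1","stable_1800s_synthetic"
1850,"                 0","                 1","stable_1800s_synthetic"
1851,"                 0","                 1","stable_1800s_synthetic"
1852,"                 0","                 1","stable_1800s_synthetic"
1853,"                 0","                 1","stable_1800s_synthetic"
1854,"                 0","                 1","stable_1800s_synthetic"
1855,"                 0","                 1","stable_1800s_synthetic"
1856,"                 0","                 1","stable_1800s_synthetic"
1857,"                 0","                 1","stable_1800s_synthetic"
1858,"                 0","                 1","stable_1800s_synthetic"
1859,"                 0","                 1","stable_1800s_synthetic"
1860,"                 0","                 1","stable_1800s_synthetic"
1861,"                 0","                 1","stable_1800s_synthetic"
1862,"                 0","                 1","stable_1800s_synthetic"
1863,"                 0","                 1","stable_1800s_synthetic"
1864,"                 0","                 1","stable_1800s_synthetic"
1865,"                 0","                 1","stable_1800s_synthetic"
1866,"                 0","                 1","stable_1800s_synthetic"
1867,"                 0","                 1","stable_1800s_synthetic"
1868,"                 0","                 1","stable_1800s_synthetic"
1869,"                 0","                 1","stable_1800s_synthetic"
1870,"                 0","                 1","stable_1800s_synthetic"
1871,"                 0","                 1","stable_1800s_synthetic"
1872,"                 0","                 1","stable_1800s_synthetic"
1873,"                 0","                 1","stable_1800s_synthetic"
1874,"                 0","                 1","stable_1800s_synthetic"
1875,"                 0","                 1","stable_1800s_synthetic"
1876,"                 0","                 1","stable_1800s_synthetic"
1877,"                 0","                 1","stable_1800s_synthetic"
1878,"                 0","                 1","stable_1800s_synthetic"
1879,"                 0","                 1","stable_1800s_synthetic"
1880,"                 0","                 1","stable_1800s_synthetic"
1881,"                 0","                 1","stable_1800s_synthetic"
1882,"                 0","                 1","stable_1800s_synthetic"
1883,"                 0","                 1","stable_1800s_synthetic"
1884,"                 0","                 1","stable_1800s_synthetic"
1885,"                 0","                 1","stable_1800s_synthetic"
1886,"                 0","                 1","stable_1800s_synthetic"
1887,"                 0","                 1","stable_1800s_synthetic"
1888,"                 0","                 1","stable_1800s_synthetic"
1889,"                 0","                 1","stable_1800s_synthetic"
1890,"                 0","                 1","stable_1800s_synthetic"
1891,"                 0","                 1","stable_1800s_synthetic"
1892,"                 0","                 1","stable_1800s_synthetic"
1893,"                 0","                 1","stable_1800s_synthetic"
1894,"                 0","                 1","stable_1800s_synthetic"
1895,"                 0","                 1","stable_1800s_synthetic"
1896,"                 0","                 1","stable_1800s_synthetic"
1897,"                 0","                 1","stable_1800s_synthetic"
1898,"                 0","                 1","stable_1800s_synthetic"
1899,"                 0","                 1","stable_1800s_synthetic"
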