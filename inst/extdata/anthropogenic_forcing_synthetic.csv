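time,rf_wm2
1990,1.7
1991,1.7085
1992,1.7183
1993,1.7285
1994,1.7392
1995,1.7501
1996,1.7612
1997,1.7725
1998,1.7839
1999,1.7955
2000,1.8073
2001,1.8191
2002,1.8311
2003,1.8432
2004,1.8553
2005,1.8676
2006,1.8799
2007,1.8923
2008,1.9048
2009,1.9174
2010,1.93
2011,1.9427
2012,1.9554
2013,1.9682
2014,1.9811
2015,1.994
2016,2.0069
2017,2.0199
2018,2.033
2019,2.0461
2020,2.0592
2021,2.0724
2022,2.0857
2023,2.099
2024,2.1123
2025,2.1256
2026,2.139
2027,2.1525
2028,2.1659
2029,2.1794
2030,2.193
2031,2.2065
2032,2.2202
2033,2.2338
2034,2.2475
2035,2.2612
2036,2.2749
2037,2.2887
2038,2.3025
2039,2.3163
2040,2.3301
2041,2.344
2042,2.3579
2043,2.3718
2044,2.3858
2045,2.3998
2046,2.4138
2047,2.4278
2048,2.4419
2049,2.456
2050,2.4701
2051,2.4842
2052,2.4983
2053,2.5125
2054,2.5267
2055,2.5409
2056,2.5552
2057,2.5694
2058,2.5837
2059,2.598
2060,2.6124
2061,2.6267
2062,2.6411
2063,2.6555
2064,2.6699
2065,2.6843
2066,2.6987
2067,2.7132
2068,2.7277
2069,2.7422
2070,2.7567
2071,2.7713
2072,2.7858
2073,2.8004
2074,2.815
2075,2.8296
2076,2.8442
2077,2.8589
2078,2.8735
2079,2.8882
2080,2.9029
2081,2.9176
2082,2.9323
2083,2.9471
2084,2.9618
2085,2.9766
2086,2.9914
2087,3.0062
2088,3.021
2089,3.0359
2090,3.0507
2091,3.0656
2092,3.0804
2093,3.0953
2094,3.1102
2095,3.1252
2096,3.1401
2097,3.1551
2098,3.17
2099,3.185
2100,3.2
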