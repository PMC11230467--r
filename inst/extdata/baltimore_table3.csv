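zone_id,count,population,injury_pct,pct_A,pct_B,pct_C,pct_D,score_printed
21061,13,55020,0.0,0.0,0.0,100.0,0.0,3.0
21090,2,9715,0.0,0.0,39.6,60.4,0.0,2.6
21201,43,17534,0.2,0.0,0.0,0.0,100.0,4.0
21202,39,21880,0.2,0.0,0.0,1.0,99.0,4.0
21204,5,21518,0.0,0.5,99.5,0.0,0.0,2.0
21205,26,15900,0.2,0.0,0.0,44.1,55.9,3.6
21206,58,51670,0.1,0.0,100.0,0.0,0.0,2.0
21207,49,50440,0.1,0.0,76.1,23.9,0.0,2.2
21208,5,35273,0.0,23.7,76.3,0.0,0.0,1.8
21209,5,28621,0.0,0.0,97.3,2.7,0.0,2.0
21210,0,16076,0.0,41.7,51.7,6.6,0.0,1.6
21211,6,15735,0.0,4.4,14.4,70.0,11.2,2.9
21212,17,33865,0.1,40.4,54.8,4.8,0.0,1.6
21213,83,30596,0.3,0.1,40.5,40.9,18.5,2.8
21214,12,21666,0.1,0.0,0.0,100.0,0.0,2.0
21215,51,55081,0.1,0.0,67.5,32.5,0.0,2.3
21216,74,28733,0.3,0.0,54.8,45.2,0.0,2.5
21217,112,32830,0.3,0.0,6.2,44.1,49.7,3.4
21218,80,46172,0.2,46.3,16.9,33.4,3.4,1.9
21222,20,56946,0.0,0.0,30.4,69.6,0.0,2.7
21223,102,21974,0.5,0.0,0.0,57.8,42.2,3.4
21224,24,48770,0.0,0.0,0.0,49.8,50.2,3.5
21225,40,33227,0.1,0.0,0.0,100.0,0.0,3.0
21226,2,6699,0.0,0.0,0.0,67.2,32.8,3.3
21227,11,33396,0.0,0.0,0.0,100.0,0.0,3.0
21228,4,49438,0.0,0.0,82.6,8.4,9.0,2.3
21229,74,45983,0.2,20.5,28.9,50.7,0.0,2.3
21230,18,33592,0.1,0.0,0.0,42.0,58.0,3.6
21231,20,15906,0.1,0.0,0.0,1.3,98.7,4.0
21234,36,68678,0.1,0.0,100.0,0.0,0.0,2.0
21236,8,37803,0.0,0.0,100.0,0.0,0.0,2.0
21237,5,31105,0.0,0.0,50.0,50.0,0.0,2.5
21244,10,36897,0.0,0.0,0.0,100.0,0.0,3.0
21251,0,2040,0.0,0.0,100.0,0.0,0.0,2.0
21252,1,19711,0.0,0.0,100.0,0.0,0.0,2.0
21286,0,1652,0.0,23.9,76.1,0.0,0.0,1.8
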