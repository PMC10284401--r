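"strain","replicate","dilution_exponent","plaque_count","spotted_volume"
"s01",1,0,NA,5
"s01",1,-2,55,5
"s01",1,-4,1,5
"s01",2,0,NA,5
"s01",2,-2,58,5
"s01",2,-4,1,5
"s01",3,0,NA,5
"s01",3,-2,61,5
"s01",3,-4,1,5
"s01",4,0,NA,5
"s01",4,-2,64,5
"s01",4,-4,1,5
"s02",1,0,NA,5
"s02",1,-2,67,5
"s02",1,-4,1,5
"s02",2,0,NA,5
"s02",2,-2,70,5
"s02",2,-4,1,5
"s02",3,0,NA,5
"s02",3,-2,73,5
"s02",3,-4,1,5
"s02",4,0,NA,5
"s02",4,-2,76,5
"s02",4,-4,1,5
"s03",1,0,NA,5
"s03",1,-2,41,5
"s03",1,-4,0,5
"s03",2,0,NA,5
"s03",2,-2,44,5
"s03",2,-4,0,5
"s03",3,0,NA,5
"s03",3,-2,47,5
"s03",3,-4,0,5
"s03",4,0,NA,5
"s03",4,-2,50,5
"s03",4,-4,0,5
"s04",1,0,NA,5
"s04",1,-2,48,5
"s04",1,-4,0,5
"s04",2,0,NA,5
"s04",2,-2,51,5
"s04",2,-4,0,5
"s04",3,0,NA,5
"s04",3,-2,54,5
"s04",3,-4,0,5
"s04",4,0,NA,5
"s04",4,-2,57,5
"s04",4,-4,0,5
"s05",1,0,NA,5
"s05",1,-2,123,5
"s05",1,-4,1,5
"s05",2,0,NA,5
"s05",2,-2,126,5
"s05",2,-4,1,5
"s05",3,0,NA,5
"s05",3,-2,129,5
"s05",3,-4,1,5
"s05",4,0,NA,5
"s05",4,-2,132,5
"s05",4,-4,1,5
"s06",1,0,NA,5
"s06",1,-2,28,5
"s06",1,-4,0,5
"s06",2,0,NA,5
"s06",2,-2,31,5
"s06",2,-4,0,5
"s06",3,0,NA,5
"s06",3,-2,34,5
"s06",3,-4,0,5
"s06",4,0,NA,5
"s06",4,-2,37,5
"s06",4,-4,0,5
"s07",1,0,0,5
"s07",1,-2,0,5
"s07",1,-4,0,5
"s07",2,0,0,5
"s07",2,-2,0,5
"s07",2,-4,0,5
"s07",3,0,0,5
"s07",3,-2,0,5
"s07",3,-4,0,5
"s07",4,0,0,5
"s07",4,-2,0,5
"s07",4,-4,0,5
"s08",1,0,0,5
"s08",1,-2,0,5
"s08",1,-4,0,5
"s08",2,0,0,5
"s08",2,-2,0,5
"s08",2,-4,0,5
"s08",3,0,0,5
"s08",3,-2,0,5
"s08",3,-4,0,5
"s08",4,0,0,5
"s08",4,-2,0,5
"s08",4,-4,0,5
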