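"strain","replicate","technical_rep","ct","melt_peak","plate"
"s01",1,1,11.9,78,"P1"
"s01",1,2,12.4,78,"P2"
"s01",2,1,12,78,"P1"
"s01",2,2,12.5,78,"P2"
"s01",3,1,12.1,78,"P1"
"s01",3,2,12.6,78,"P2"
"s01",4,1,12.2,78,"P1"
"s01",4,2,12.7,78,"P2"
"s02",1,1,12.9,78,"P1"
"s02",1,2,13.4,78,"P2"
"s02",2,1,13,78,"P1"
"s02",2,2,13.5,78,"P2"
"s02",3,1,13.1,78,"P1"
"s02",3,2,13.6,78,"P2"
"s02",4,1,13.2,78,"P1"
"s02",4,2,13.7,78,"P2"
"s03",1,1,14.9,78,"P1"
"s03",1,2,15.4,78,"P2"
"s03",2,1,15,78,"P1"
"s03",2,2,15.5,78,"P2"
"s03",3,1,15.1,78,"P1"
"s03",3,2,15.6,78,"P2"
"s03",4,1,15.2,78,"P1"
"s03",4,2,15.7,78,"P2"
"s04",1,1,15.9,78,"P1"
"s04",1,2,16.4,78,"P2"
"s04",2,1,16,78,"P1"
"s04",2,2,16.5,78,"P2"
"s04",3,1,16.1,78,"P1"
"s04",3,2,16.6,78,"P2"
"s04",4,1,16.2,78,"P1"
"s04",4,2,16.7,78,"P2"
"s05",1,1,10.9,78,"P1"
"s05",1,2,11.4,82.5,"P2"
"s05",2,1,11,78,"P1"
"s05",2,2,11.5,78,"P2"
"s05",3,1,11.1,78,"P1"
"s05",3,2,11.6,78,"P2"
"s05",4,1,11.2,78,"P1"
"s05",4,2,11.7,78,"P2"
"s06",1,1,16.9,78,"P1"
"s06",1,2,17.4,78,"P2"
"s06",2,1,17,78,"P1"
"s06",2,2,17.5,78,"P2"
"s06",3,1,17.1,78,"P1"
"s06",3,2,17.6,78,"P2"
"s06",4,1,17.2,78,"P1"
"s06",4,2,17.7,78,"P2"
"s07",1,1,20.4,78,"P1"
"s07",1,2,20.9,78,"P2"
"s07",2,1,NA,78,"P1"
"s07",2,2,21,78,"P2"
"s07",3,1,20.6,78,"P1"
"s07",3,2,21.1,78,"P2"
"s07",4,1,20.7,78,"P1"
"s07",4,2,21.2,78,"P2"
"s08",1,1,20.1,78,"P1"
"s08",1,2,20.6,78,"P2"
"s08",2,1,20.2,78,"P1"
"s08",2,2,20.7,78,"P2"
"s08",3,1,20.3,78,"P1"
"s08",3,2,20.8,78,"P2"
"s08",4,1,20.4,78,"P1"
"s08",4,2,20.9,78,"P2"
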