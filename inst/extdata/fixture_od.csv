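"strain","replicate","od_infected","od_uninfected"
"s01",1,0.2042,1.23
"s01",2,0.1991,1.26
"s01",3,0.1935,1.29
"s01",4,0.1874,1.32
"s01",5,0.1809,1.35
"s01",6,0.1739,1.38
"s02",1,0.2903,1.23
"s02",2,0.2873,1.26
"s02",3,0.2838,1.29
"s02",4,0.2798,1.32
"s02",5,0.2754,1.35
"s02",6,0.2705,1.38
"s03",1,0.5117,1.23
"s03",2,0.5141,1.26
"s03",3,0.516,1.29
"s03",4,4.62,1.32
"s03",5,0.5184,1.35
"s03",6,0.5189,1.38
"s04",1,0.5732,1.23
"s04",2,0.5771,1.26
"s04",3,0.5805,1.29
"s04",4,0.5834,1.32
"s04",5,0.5859,1.35
"s04",6,0.5879,1.38
"s05",1,0.1427,1.23
"s05",2,0.1361,1.26
"s05",3,0.129,1.29
"s05",4,0.1214,1.32
"s05",5,0.1134,1.35
"s05",6,0.1049,1.38
"s06",1,0.7577,1.23
"s06",2,0.8442,1.26
"s06",3,0.774,1.29
"s06",4,0.7814,1.32
"s06",5,0.7884,1.35
"s06",6,0.7949,1.38
"s07",1,1.2128,1.23
"s07",2,1.2323,1.26
"s07",3,1.2513,1.29
"s07",4,1.2698,1.32
"s07",5,1.2879,1.35
"s07",6,1.3055,1.38
"s08",1,1.1882,1.23
"s08",2,1.2071,1.26
"s08",3,1.2255,1.29
"s08",4,1.2434,1.32
"s08",5,1.2609,1.35
"s08",6,1.2779,1.38
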