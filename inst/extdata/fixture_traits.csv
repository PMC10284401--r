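"strain","trait","replicate","value"
"s01","OD",1,0.833983739837398
"s01","OD",2,0.841984126984127
"s01","OD",3,0.85
"s01","OD",4,0.858030303030303
"s01","OD",5,0.866
"s01","OD",6,0.873985507246377
"s01","PA_binary",1,1
"s01","PA_binary",2,1
"s01","PA_binary",3,1
"s01","PA_binary",4,1
"s01","PA_cont",1,3.30102999566398
"s01","PA_cont",2,3.30102999566398
"s01","PA_cont",3,3.30102999566398
"s01","PA_cont",4,3.30102999566398
"s01","qPCR",1,2.36308546596225
"s01","qPCR",2,2.33298246639585
"s01","qPCR",3,2.30287946682946
"s01","qPCR",4,2.27277646726306
"s02","OD",1,0.763983739837398
"s02","OD",2,0.771984126984127
"s02","OD",3,0.78
"s02","OD",4,0.788030303030303
"s02","OD",5,0.796
"s02","OD",6,0.803985507246377
"s02","PA_binary",1,1
"s02","PA_binary",2,1
"s02","PA_binary",3,1
"s02","PA_binary",4,1
"s02","PA_cont",1,3.30102999566398
"s02","PA_cont",2,3.30102999566398
"s02","PA_cont",3,3.30102999566398
"s02","PA_cont",4,3.30102999566398
"s02","qPCR",1,2.06205547029827
"s02","qPCR",2,2.03195247073187
"s02","qPCR",3,2.00184947116548
"s02","qPCR",4,1.97174647159908
"s03","OD",1,0.583983739837398
"s03","OD",2,0.591984126984127
"s03","OD",3,0.6
"s03","OD",5,0.616
"s03","OD",6,0.623985507246377
"s03","PA_binary",1,1
"s03","PA_binary",2,1
"s03","PA_binary",3,1
"s03","PA_binary",4,1
"s03","PA_cont",1,2.91381385238372
"s03","PA_cont",2,2.94448267215017
"s03","PA_cont",3,2.9731278535997
"s03","PA_cont",4,3
"s03","qPCR",1,1.45999547897031
"s03","qPCR",2,1.42989247940391
"s03","qPCR",3,1.39978947983751
"s03","qPCR",4,1.36968648027111
"s04","OD",1,0.533983739837398
"s04","OD",2,0.541984126984127
"s04","OD",3,0.55
"s04","OD",4,0.558030303030303
"s04","OD",5,0.566
"s04","OD",6,0.573985507246377
"s04","PA_binary",1,1
"s04","PA_binary",2,1
"s04","PA_binary",3,1
"s04","PA_binary",4,1
"s04","PA_cont",1,2.98227123303957
"s04","PA_cont",2,3.00860017176192
"s04","PA_cont",3,3.03342375548695
"s04","PA_cont",4,3.05690485133647
"s04","qPCR",1,1.15896548330633
"s04","qPCR",2,1.12886248373993
"s04","qPCR",3,1.09875948417353
"s04","qPCR",4,1.06865648460713
"s05","OD",1,0.883983739837398
"s05","OD",2,0.891984126984127
"s05","OD",3,0.9
"s05","OD",4,0.908030303030303
"s05","OD",5,0.916
"s05","OD",6,0.923985507246377
"s05","PA_binary",1,1
"s05","PA_binary",2,1
"s05","PA_binary",3,1
"s05","PA_binary",4,1
"s05","PA_cont",1,3.30102999566398
"s05","PA_cont",2,3.30102999566398
"s05","PA_cont",3,3.30102999566398
"s05","PA_cont",4,3.30102999566398
"s05","qPCR",1,2.66411546162623
"s05","qPCR",2,2.63401246205984
"s05","qPCR",3,2.60390946249344
"s05","qPCR",4,2.57380646292704
"s06","OD",1,0.383983739837398
"s06","OD",3,0.4
"s06","OD",4,0.408030303030303
"s06","OD",5,0.416
"s06","OD",6,0.423985507246377
"s06","PA_binary",1,1
"s06","PA_binary",2,1
"s06","PA_binary",3,1
"s06","PA_binary",4,1
"s06","PA_cont",1,2.7481880270062
"s06","PA_cont",2,2.79239168949825
"s06","PA_cont",3,2.83250891270624
"s06","PA_cont",4,2.86923171973098
"s06","qPCR",1,0.857935487642347
"s06","qPCR",2,0.827832488075948
"s06","qPCR",3,0.79772948850955
"s06","qPCR",4,0.767626488943152
"s07","OD",1,0.0139837398373983
"s07","OD",2,0.021984126984127
"s07","OD",3,0.03
"s07","OD",4,0.038030303030303
"s07","OD",5,0.046
"s07","OD",6,0.0539855072463767
"s07","PA_binary",1,0
"s07","PA_binary",2,0
"s07","PA_binary",3,0
"s07","PA_binary",4,0
"s07","qPCR",1,-0.195669497181587
"s07","qPCR",2,-0.225772496747986
"s07","qPCR",3,-0.255875496314384
"s07","qPCR",4,-0.285978495880782
"s08","OD",1,0.0339837398373984
"s08","OD",2,0.0419841269841269
"s08","OD",3,0.05
"s08","OD",4,0.058030303030303
"s08","OD",5,0.0660000000000001
"s08","OD",6,0.0739855072463767
"s08","PA_binary",1,0
"s08","PA_binary",2,0
"s08","PA_binary",3,0
"s08","PA_binary",4,0
"s08","qPCR",1,-0.105360498482394
"s08","qPCR",2,-0.135463498048791
"s08","qPCR",3,-0.16556649761519
"s08","qPCR",4,-0.195669497181587
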