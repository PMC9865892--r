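system,temperature_C,class,total,total_sd,n_molecules
UL,35,lipid-lipid,217,8,128
UL,65,lipid-lipid,183,11,128
ML,35,lipid-lipid,219,7,128
ML,65,lipid-lipid,190,10,128
UL,35,water-water,9604,45,6400
UL,65,water-water,9061,54,6400
ML,35,water-water,3630,31,2781
ML,65,water-water,3371,35,2781
UL,35,water-lipid,1315,24,NA
UL,65,water-lipid,1430,37,NA
ML,35,water-lipid,1296,23,NA
ML,65,water-lipid,1395,33,NA
UL,35,water-PO2,346,12,NA
UL,65,water-PO2,398,16,NA
ML,35,water-PO2,348,12,NA
ML,65,water-PO2,390,15,NA
UL,35,water-C=O,130,9,NA
UL,65,water-C=O,179,11,NA
ML,35,water-C=O,123,9,NA
ML,65,water-C=O,175,10,NA
UL,35,water-COO,552,13,NA
UL,65,water-COO,537,17,NA
ML,35,water-COO,544,13,NA
ML,65,water-COO,523,16,NA
UL,35,water-glycerol,147,9,NA
UL,65,water-glycerol,202,11,NA
ML,35,water-glycerol,139,10,NA
ML,65,water-glycerol,197,11,NA
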