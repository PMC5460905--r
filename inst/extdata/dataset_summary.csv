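gene,train_actives,train_decoys,train_total,train_tanimoto,test_actives,test_decoys,test_total,test_tanimoto
HTR2A,2200,6600,8800,0.288,742,2226,2968,0.198
ADORA2A,2360,7080,9440,0.279,783,2349,3132,0.179
CHRM2,380,1140,1520,0.249,128,384,512,0.15
PDE9A,110,330,440,0.114,33,99,132,0.046
GRM2,310,930,1240,0.28,106,318,424,0.234
GRM3,50,150,200,0.305,16,48,64,0.203
MAPK8,780,2340,3120,0.192,266,798,1064,0.091
MAPK9,330,990,1320,0.13,108,324,432,0.06
MAPK10,510,1530,2040,0.183,174,522,696,0.056
MAPK14,40,120,160,0.181,19,57,76,0.171
HS90AA1,750,2250,3000,0.215,248,744,992,0.1361
PIN1,60,180,240,0.125,23,69,92,0.0544
MAPT,40,120,160,0.1125,12,36,48,0.0209
PTGS2,1760,5280,7040,0.542,583,1749,2332,0.164
NOS2,570,1710,2280,0.33,184,552,736,0.288
MPO,60,180,240,0.338,19,57,76,0.211
CHUK,120,360,480,0.173,41,123,164,0.098
IKBKB,600,1800,2400,0.22,198,594,792,0.123
TNF,560,1680,2240,0.184,192,576,768,0.083
ALOX12,120,360,480,0.2,40,120,160,0.119
CTSD,1250,3750,5000,0.246,423,1269,1692,0.093
PDK1,440,1320,1760,0.261,149,447,596,0.2
HMGCR,600,1800,2400,0.233,199,597,796,0.136
IDE,60,180,240,0.054,20,60,80,0.013
PPARG,1730,5190,6920,0.264,582,1746,2328,0.171
CES1,290,870,1160,0.305,100,300,400,0.27
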