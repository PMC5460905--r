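gene,nb_ecfp6_mcc,nb_ecfp6_auc,rp_ecfp6_mcc,rp_ecfp6_auc,nb_maccs_mcc,nb_maccs_auc,rp_maccs_mcc,rp_maccs_auc
HTR2A,0.992,1,0.944,0.988,0.732,0.948,0.938,0.989
ADORA2A,0.989,1,0.947,0.989,0.89,0.981,0.984,0.995
CHRM2,0.984,0.999,0.877,0.976,0.779,0.963,0.928,0.978
PDE9A,0.994,0.999,0.913,0.97,0.939,0.993,0.947,0.971
GRM2,0.989,1,0.955,0.987,0.754,0.962,0.892,0.979
GRM3,1,1,0.882,0.968,0.906,0.984,0.889,0.961
MAPK8,0.991,1,0.916,0.973,0.707,0.941,0.893,0.966
MAPK9,0.98,0.996,0.852,0.961,0.763,0.945,0.822,0.939
MAPK10,0.952,0.993,0.866,0.956,0.65,0.915,0.849,0.943
MAPK14,1,1,0.905,0.935,0.916,0.98,0.795,0.897
HS90AA1,0.975,0.997,0.928,0.984,0.689,0.941,0.911,0.97
PIN1,0.978,0.999,0.914,0.964,0.978,0.998,0.812,0.922
MAPT,0.937,0.998,0.725,0.886,0.794,0.904,0.724,0.815
PTGS2,0.956,0.997,0.93,0.982,0.698,0.935,0.965,0.991
NOS2,0.976,0.999,0.886,0.968,0.702,0.929,0.887,0.97
MPO,0.956,0.996,0.914,0.963,0.781,0.956,0.918,0.953
CHUK,0.983,0.992,0.955,0.961,0.729,0.971,0.882,0.947
IKBKB,0.993,1,0.932,0.983,0.775,0.954,0.905,0.967
TNF,0.867,0.985,0.814,0.933,0.564,0.854,0.798,0.938
ALOX12,0.989,1,0.924,0.98,0.88,0.986,0.936,0.989
CTSD,0.961,0.994,0.976,0.994,0.729,0.949,0.942,0.992
PDK1,0.995,0.997,0.981,0.996,0.985,0.994,0.983,0.991
HMGCR,0.991,1,0.974,0.996,0.935,0.998,0.97,0.995
IDE,0.851,0.988,0.679,0.881,0.68,0.923,0.753,0.829
PPARG,0.981,0.998,0.955,0.991,0.745,0.947,0.934,0.988
CES1,0.956,0.999,0.934,0.972,0.676,0.913,0.89,0.969
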