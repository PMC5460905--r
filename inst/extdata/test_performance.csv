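gene,nb_ecfp6_mcc,nb_ecfp6_auc,rp_ecfp6_mcc,rp_ecfp6_auc,nb_maccs_mcc,nb_maccs_auc,rp_maccs_mcc,rp_maccs_auc
HTR2A,0.953,0.997,0.884,0.967,0.678,0.931,0.838,0.959
ADORA2A,0.653,0.949,0.681,0.911,0.553,0.868,0.26,0.714
CHRM2,0.797,0.961,0.738,0.889,0.664,0.915,0.651,0.939
PDE9A,0.96,0.994,0.836,0.954,0.643,0.982,0.771,0.855
GRM2,0.956,0.989,0.893,0.955,0.544,0.876,0.687,0.917
GRM3,0.832,0.897,0.797,0.911,0.785,0.874,0.788,0.847
MAPK8,0.927,0.991,0.801,0.928,0.651,0.903,0.746,0.898
MAPK9,0.829,0.956,0.681,0.869,0.633,0.901,0.615,0.874
MAPK10,0.787,0.937,0.695,0.879,0.541,0.852,0.594,0.84
MAPK14,0.965,0.984,0.894,0.921,0.75,0.935,0.393,0.7
HS90AA1,0.821,0.935,0.807,0.897,0.585,0.88,0.745,0.857
PIN1,0.854,0.964,0.791,0.906,0.728,0.899,0.698,0.887
MAPT,0.832,0.97,0.408,0.748,0.591,0.854,0.415,0.779
PTGS2,0.854,0.983,0.756,0.919,0.587,0.874,0.898,0.976
NOS2,0.893,0.983,0.752,0.901,0.543,0.841,0.668,0.894
MPO,0.787,0.994,0.666,0.865,0.383,0.629,0.492,0.752
CHUK,0.735,0.939,0.731,0.856,0.726,0.928,0.677,0.921
IKBKB,0.895,0.973,0.832,0.911,0.696,0.907,0.718,0.915
TNF,0.697,0.915,0.501,0.791,0.171,0.722,0.502,0.814
ALOX12,0.849,0.97,0.752,0.906,0.718,0.901,0.804,0.932
CTSD,0.885,0.974,0.92,0.95,0.647,0.913,0.867,0.941
PDK1,0.946,0.959,0.955,0.976,0.923,0.961,0.937,0.955
HMGCR,0.964,1,0.963,0.987,0.913,0.995,0.929,0.984
IDE,0.864,0.983,0.321,0.729,0.114,0.69,0.401,0.704
PPARG,0.897,0.965,0.884,0.948,0.661,0.916,0.803,0.928
CES1,0.683,0.929,0.809,0.919,0.472,0.792,0.662,0.861
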