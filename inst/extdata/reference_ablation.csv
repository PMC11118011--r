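variant,tp_g23,fp_g23,fn_g23,tn_g23,tp_g456,fp_g456,fn_g456,tn_g456,accuracy,sensitivity,specificity,auc
DysDiTect_PLAG,25,10,3,24,11,2,9,23,0.776,0.750,0.797,0.883
DysDiTect_PLA,24,6,4,28,14,2,6,23,0.832,0.792,0.864,0.912
DysDiTect_PLG,17,4,11,30,8,0,12,25,0.748,0.521,0.932,0.823
DysDiTect_PL,23,7,5,27,11,1,9,24,0.794,0.708,0.864,0.888
DysDiTect_PAG,26,4,2,30,14,4,6,21,0.850,0.833,0.864,0.898
DysDiTect_PA,22,8,6,26,7,1,13,24,0.738,0.604,0.847,0.805
DysDiTect_PG,15,3,13,31,5,0,15,25,0.710,0.417,0.949,0.820
DysDiTect_P,21,5,7,29,10,6,10,19,0.738,0.646,0.814,0.769
DysDiTect_LAG,24,6,4,28,14,2,6,23,0.832,0.792,0.864,0.922
DysDiTect_LA,22,4,6,30,13,2,7,23,0.822,0.729,0.898,0.901
DysDiTect_LG,25,9,3,25,9,1,11,24,0.776,0.708,0.831,0.833
DysDiTect_L,22,4,6,30,9,0,11,25,0.804,0.646,0.932,0.855
DysDiTect_AG,25,9,3,25,7,3,13,22,0.738,0.667,0.797,0.832
DysDiTect_A,25,11,3,23,11,2,9,23,0.766,0.750,0.780,0.823
DysDiTect_G,24,10,4,24,10,3,10,22,0.748,0.708,0.780,0.809
DysDiTect_,21,9,7,25,10,2,10,23,0.738,0.646,0.814,0.858
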