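# UNIFAC VLE subgroup volume (R) and surface-area (Q) parameters,
# Hansen et al. (1991) revision of the original published table.
# main_group ids follow the published numbering (1 CH2, 3 ACH, 4 ACCH2,
# 5 OH, 8 ACOH, 9 CH2CO). n_C/n_H/n_O: atoms per subgroup occurrence.
subgroup,main_group,main_name,R,Q,n_C,n_H,n_O
CH3,1,CH2,0.9011,0.848,1,3,0
CH2,1,CH2,0.6744,0.540,1,2,0
CH,1,CH2,0.4469,0.228,1,1,0
C,1,CH2,0.2195,0.000,1,0,0
ACH,3,ACH,0.5313,0.400,1,1,0
AC,3,ACH,0.3652,0.120,1,0,0
ACCH3,4,ACCH2,1.2663,0.968,2,3,0
ACCH2,4,ACCH2,1.0396,0.660,2,2,0
ACCH,4,ACCH2,0.8121,0.348,2,1,0
OH,5,OH,1.0000,1.200,0,1,1
ACOH,8,ACOH,0.8952,0.680,1,1,1
CH3CO,9,CH2CO,1.6724,1.488,2,3,1
CH2CO,9,CH2CO,1.4457,1.180,2,2,1
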