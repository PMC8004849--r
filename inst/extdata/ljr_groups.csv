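# Modified Lydersen-Joback-Reid group contributions.
# dtb_K: Joback-Reid normal-boiling-point contribution (K), Tb = 198.2 + sum.
# dtc, dpc_bar, dvc_cm3_mol: Modified-Lydersen contributions,
#   Tc = Tb / (0.5703 + 1.0121*sum(dtc) - sum(dtc)^2)
#   Pc = M / (0.2573 + sum(dpc_bar))^2   [bar, M in g/mol]
#   Vc = 6.75 + sum(dvc_cm3_mol)         [cm3/mol]
# n_C, n_H, n_O: atoms contributed per group occurrence (for balance checks).
group,dtb_K,dtc,dpc_bar,dvc_cm3_mol,n_C,n_H,n_O
CH3,23.58,0.0275,0.3031,66.81,1,3,0
CH2,22.88,0.0159,0.2165,57.11,1,2,0
CH,21.74,0.0002,0.1140,45.70,1,1,0
C,18.18,-0.0206,0.0539,21.78,1,0,0
=CH2,24.96,0.0170,0.2493,60.37,1,2,0
=CH,18.25,0.0182,0.1866,49.92,1,1,0
=C,24.14,-0.0003,0.0832,34.90,1,0,0
OH,92.88,0.0741,0.1500,30.40,0,1,1
O,22.42,0.0051,0.1056,15.61,0,0,1
C=O,94.97,0.0375,0.2341,69.76,1,0,1
CHO,72.24,0.0379,0.3128,77.46,1,1,1
COOH,169.06,0.0695,0.4387,88.60,1,1,2
ring_CH2,27.15,0.0116,0.1982,51.64,1,2,0
ring_CH,21.78,0.0081,0.1773,30.56,1,1,0
ring_C,21.32,-0.0180,0.0139,17.62,1,0,0
ring_=CH,26.73,0.0114,0.1693,42.55,1,1,0
ring_=C,31.01,0.0051,0.0955,31.28,1,0,0
ring_C=O,94.97,0.0284,0.2021,62.38,1,0,1
OH_phenol,76.34,0.0240,0.0184,-25.73,0,1,1
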