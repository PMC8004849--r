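# Compound and binary-system definitions for the four terpene eutectic
# solvent systems. Field names carry explicit units (t_fus_K, dh_fus_kJ_per_mol).
# Enthalpies of fusion are stored in kJ/mol: the published table header says
# J/mol, but only the kJ/mol reading reproduces the published ideal eutectics.
compounds:
  - name: menthol
    formula: C10H20O
    t_fus_K: 309.72
    dh_fus_kJ_per_mol: 13.62
    unifac_groups: {CH3: 3, CH2: 3, CH: 4, OH: 1}
    ljr_groups: {CH3: 3, CH: 1, ring_CH2: 3, ring_CH: 3, OH: 1}
  - name: thymol
    formula: C10H14O
    t_fus_K: 324.31
    dh_fus_kJ_per_mol: 18.54
    unifac_groups: {ACH: 3, ACCH3: 1, ACCH: 1, CH3: 2, ACOH: 1}
    ljr_groups: {CH3: 3, CH: 1, "ring_=CH": 3, "ring_=C": 3, OH_phenol: 1}
  - name: borneol
    formula: C10H18O
    t_fus_K: 481.33
    dh_fus_kJ_per_mol: 7.23
    unifac_groups: {CH3: 3, CH2: 3, CH: 2, C: 2, OH: 1}
    ljr_groups: {CH3: 3, ring_CH2: 3, ring_CH: 2, ring_C: 2, OH: 1}
  - name: camphor
    formula: C10H16O
    t_fus_K: 452.41
    dh_fus_kJ_per_mol: 6.32
    unifac_groups: {CH3: 3, CH2: 2, CH: 1, C: 2, CH2CO: 1}
    ljr_groups: {CH3: 3, ring_CH2: 3, ring_CH: 1, ring_C: 2, "ring_C=O": 1}
systems:
  - label: "Men:Bor"
    comp_i: menthol
    comp_j: borneol
    x_i: 0.7
  - label: "Men:Cam"
    comp_i: menthol
    comp_j: camphor
    x_i: 0.6
  - label: "Thy:Bor"
    comp_i: thymol
    comp_j: borneol
    x_i: 0.7
  - label: "Thy:Cam"
    comp_i: thymol
    comp_j: camphor
    x_i: 0.5
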