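k_ph: 0.702743
k_dp0: 0.0010037
k_dpG: 0.096519
k_smA0: 0.0815697
k_smA: 0.1120422
k_dmA: 0.0412138
k_sA: 0.0364107
k_GA: 10.6547313
k_CA: 36.1596879
k_dA: 0.0096939
k_smC0: 0.0020444
k_smC: 0.0935273
k_dmC: 0.0213697
k_sC: 0.0063009
k_SC: 0.1131622
k_dC: 0.047931
k_smG0: 0.223854
k_smG: 0.0348202
k_dmG: 0.2457665
k_sG: 0.0014224
k_CG: 42.1172928
k_dG: 0.0514183
gadd34_to_atf4: yes
chop_to_atf4: yes
chop_to_gadd34: yes
gadd34_to_eif2aP: yes
meta_note: calibrated full-variant default parameter set
meta_calibration: seeded randomized search with local refinement against the shipped
  constraint set
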