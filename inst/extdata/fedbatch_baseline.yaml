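vessel:
  t_h: 0.0
  V_L_L: 1.0
  c_SL_g_L: 0.0
  c_NL_g_L: 0.0
  c_AL_g_L: 0.0
  c_DL_mol_L: 0.5
reservoir:
  c_SR_g_L: 10.0
  c_DR_mol_L: 6.0
  V_R_L: 0.5
kinetics:
  mode: constant
  k_r: 1.0
  k_a: 1.0
  n_agg: 2
feed:
  type: constant
  F_R_L_h: 0.1
simulation:
  t_end_h: 20.0
  dt_h: 0.05
  seed: 1
sensors:
- preset: hplc_species
  quantity: c_SL
- preset: ftir_native
  quantity: c_NL
- preset: dls_aggregate
  quantity: c_AL
observer:
  filter: ukf
  process_noise: 1.0e-06
  P0_diag: 1.0e-04
  dt_h: 0.1
objective:
  w_Y: 1.0
  w_STY: 0.0
  Y_ref: 1.0
  STY_ref: 0.0
  F_min_L_h: 0.0
  F_max_L_h: 0.3
  dF_max_L_h: 0.1
  V_max_L: 2.0
  horizon: 5
  dt_c_h: 0.25
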