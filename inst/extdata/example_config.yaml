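# Example run configuration (SI units throughout).
# geometry: disc-shaped cleft with central transmissive zone.
geometry:
  R_m: 3.0e-7        # transmissive-zone radius (300 nm)
  S_m: 3.0e-6        # outer synapse radius (3 um)
  h_m: 4.0e-8        # cleft height (40 nm)
transport:
  # free aqueous Zn2+ diffusion and 3.5x / 10x cleft-hindered values
  D_m2_per_s: [7.0e-10, 2.0e-10, 7.0e-11]
  # optional immobile buffer: uncomment to halve the effective coefficient
  # buffer:
  #   c_B_mol_per_m3: 1.0
  #   k_on_per_M_s: 1.0e8
  #   k_off_per_s: 1.0e5
source:
  # mean volumetric release rate inside r <= R at release probability 1;
  # alternatively give mean_ion_rate_per_s (converted via pi R^2 h)
  k_mol_per_m3_s: 200
schedule:
  frequency_hz: 100
  pulse_duration_s: 5.0e-3
  train_duration_s: 1.0
  release_probability: 0.5
  mode: expected
uptake:
  enabled: true
  J_max_mol_per_m2_s: 3.0e-6
  K_m_mol_per_m3: 1.0
solver:
  n_cells: 300
  dt_s: auto
  t_end_s: 0.1
seed: 1
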