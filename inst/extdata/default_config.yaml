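# Default run configuration.
# Layer Cole-Cole baselines are representative low-kHz values for human skin
# layers from the dielectric-dispersion literature (stratum corneum highly
# resistive; viable epidermis/dermis ~0.2-0.3 S/m; subcutaneous fat ~0.03 S/m
# at the 5 kHz effective frequency). They are data, not code.
schema_version: 1
effective_frequency_hz: 5000.0    # 1 / (2 x 100 us phase width)
layers:
  - name: stratum_corneum
    thickness_mm: 0.029
    sigma_inf: 1.5e-4
    sigma_0: 5.0e-5
    tau: 7.96e-6
    alpha: 0.2
    rel_permittivity: 1.0e3
  - name: viable_epidermis
    thickness_mm: 0.089
    sigma_inf: 0.15
    sigma_0: 0.10
    tau: 7.96e-6
    alpha: 0.2
    rel_permittivity: 1.0e4
  - name: dermis
    thickness_mm: 1.380
    sigma_inf: 0.20
    sigma_0: 0.15
    tau: 7.96e-6
    alpha: 0.2
    rel_permittivity: 1.0e4
  - name: subcutaneous
    thickness_mm: 3.500
    sigma_inf: 0.02
    sigma_0: 0.015
    tau: 1.59e-5
    alpha: 0.3
    rel_permittivity: 5.0e3
personalization:
  a1: 0.15
  a2: -0.05
  a3: 0.05
  g_min: 0.5
  g_max: 1.5
solver:
  lateral_extent_mm: [28.0, 20.0]   # x spans the 3-electrode axis
  dx_mm: 0.7
  layer_cells: [2, 2, 6, 7]
  region: below_stratum_corneum
  tol: 1.0e-8
  drive_current_ma: 2.0
  return: bottom_face
fiber:
  diameter_um: 9.0
  internode_mm: 0.9                 # 100 x fiber diameter
  n_nodes: 21
  depth_mm: 0.8                     # mid-dermis
  nodal_gap_um: 2.5
  axoplasm_resistivity_ohm_cm: 110.0
  membrane_capacitance_uF_cm2: 2.0
  membrane_conductance_mS_cm2: 30.4
cable:
  v_rest_mv: -70.0
  v_th_mv: -55.0
  k_per_mv: 0.05
waveform:
  phase_width_us: 100.0
  amplitude_ma: 2.0
  polarity: cathodic_first
  window_us: 600.0
scoring:
  epsilon: 1.0e-9
  normalize_descriptors: false
model_selection:
  folds: 5
  seed: 7
behavior:
  chance_rate: 0.2
  n_trials_per_config: 15
  beta0: 0.3
  beta1: 1.0
  cap: 0.95
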