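# Scaled-down demonstration run: two groups of 6, 8x8x8 grid, 20 statements.
seed: 1
n_perm: 500
q_level: 0.05
min_distance_mm: 10
cutoff_hz: 0.01
motion_frac: 0.25
motion_threshold_mm: 0.5
simulation:
  n_per_group: 6
  grid_shape: [8, 8, 8]
  n_statements: 20
  polarized_region_spec:
    - center: [3, 3, 3]
      radius: 1.5
      type: both
  common_region_spec:
    - center: [6, 6, 6]
      radius: 1.5
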