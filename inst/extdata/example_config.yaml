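seed: 1.0
target_charge: 10.0
sasa_threshold: 50.0
sasa_probe: 1.4
ccs_probe: 1.0
contact_cutoff: 3.5
hbond_distance: 3.5
hbond_angle: 30.0
tail_fraction: 0.1
presence_threshold: 0.5
neighbor_mode: sequence
n_orientations: 32.0
selection: calpha
scenario:
  generate: yes
  n_res_per_chain: 24.0
  n_replicas: 6.0
  n_frames: 30.0
  t_max: 500.0
  s_vacuum: 0.96
  s_rehydrated: 0.9875
  jitter_sigma: 0.3
  loop_boost: 3.0
  persistent_fraction: 0.1
output_dir: ~
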