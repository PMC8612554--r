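# Demo configuration for the pocketdyn pipeline.
# Run with:  Rscript -e 'pocketdyn::run_pipeline("demo_config.yaml")'
seed: 1
output_dir: pocketdyn_demo
stages: [simulate, stacking, hbonds, distances, events]

toy_pocket:
  plate_gap: 3.4          # A, aromatic stacking separation
  door_front_width: 12.0  # A, target d_5-11
  door_back_width: 7.5    # A, target d_15-30
  hbond_distance: 2.9     # A, donor-acceptor distance of formed bonds

program:
  n_frames: 500
  positional_noise_sd: 0.1
  state_switch_probability: 0.5
  stacking: {G5: 0.95, G11: 0.98, C16: 0.97}
  hbonds: {U6: 0.85, C15: 0.90, A29: 0.88}

thresholds:
  r_unbind: 9             # A
  r_rebind: 1             # A
  hbond_distance_cutoff: 3.5
  hbond_angle_cutoff: 120
  stacking_margin: 0.5

events:
  n_trajectories: 3
  n_steps: 60000
  front_barrier: 3        # kcal/mol
  back_barrier: 5         # kcal/mol
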