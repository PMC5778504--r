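name: free_dna
alternation_rate_hz: 100.0
n_molecules: 100
max_duration_s: 10.0
seed: 1
photophysics:
  photons_per_frame_dex: 100.0
  photons_per_frame_aex: 70.0
  donor_bleach_rate: 0.03
  acceptor_bleach_rate: 0.1
  blink_on_rate: 0.0
  blink_off_rate: 0.0
  quench_states: []
  quench_factor: 1.0
  background_per_channel: 20.0
  camera_gain: 4.55
  read_noise_sd: 10.0
  excess_noise_factor: 2.0
  shot_noise: yes
subpopulations:
- proportion: 1.0
  label: free_dna
  scheme:
    state_labels: free_dna
    state_fret: 0.17
    state_category: closed
    rate_matrix:
      free_dna: -0.0
    initial_distribution: 1.0
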