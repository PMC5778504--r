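name: d32_dsDNA
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
- proportion: 0.5
  label: static_open
  scheme:
    state_labels: static_open
    state_fret: 0.45
    state_category: open
    rate_matrix:
      static_open: -0.0
    initial_distribution: 1.0
- proportion: 0.2
  label: static_closed
  scheme:
    state_labels: static_closed
    state_fret: 0.2
    state_category: closed
    rate_matrix:
      static_closed: -0.0
    initial_distribution: 1.0
- proportion: 0.05
  label: static_mid
  scheme:
    state_labels: static_mid
    state_fret: 0.35
    state_category: intermediate
    rate_matrix:
      static_mid: -0.0
    initial_distribution: 1.0
- proportion: 0.25
  label: dynamic
  scheme:
    state_labels:
    - closed
    - open1
    - open2
    state_fret:
    - 0.2
    - 0.45
    - 0.45
    state_category:
    - closed
    - open
    - open
    rate_matrix:
      closed:
      - -19.2
      - 9.6
      - 9.6
      open1:
      - 13.6363636
      - -13.6363636
      - 0.0
      open2:
      - 3.0
      - 0.0
      - -3.0
    initial_distribution:
    - 0.2039152
    - 0.1435563
    - 0.6525285
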