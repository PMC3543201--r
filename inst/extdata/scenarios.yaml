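# Frozen simulation scenarios (versioned data).
# Rates in spikes/s, times in ms relative to key release.
#
# "paperlike" tuning dispersion is calibrated so that continuous decoding is
# highly accurate at 75-150 ms windows, degrades strongly at 25 ms windows,
# and gives near-identical direct and hierarchical performance; the
# ingredients are moderate grasp-modulated rates, overlapping tuning within
# the merged object triplet, and a 10 Hz phase-locked rate rhythm whose
# random trial phase cancels over full cycles but not within short windows.
separable:
  set: original
  n_neurons: 36
  n_repetitions: 8
  seed: 2011
  tuning:
    baseline_rate_mean: 14
    baseline_rate_shape: 8
    peak_rate_mean: 150
    peak_rate_shape: 30
    within_group_share: [0.0, 0.15]
    across_group_share: [0.0, 0.15]
    onset_latency_mean: -550
    onset_latency_sd: 0.001
    onset_latency_range: [-550, -550]
    rise_time_range: [15, 25]
    rate_jitter_sd: 0
    osc_locking: 0
paperlike:
  set: original
  n_neurons: 36
  n_repetitions: 8
  seed: 2012
  tuning:
    baseline_rate_mean: 12
    baseline_rate_shape: 4
    peak_rate_mean: 65
    peak_rate_shape: 10
    within_group_share: [0.15, 0.45]
    across_group_share: [0.0, 0.2]
    onset_latency_mean: -550
    onset_latency_sd: 40
    onset_latency_range: [-630, -470]
    rise_time_range: [30, 50]
    rate_jitter_sd: 0
    osc_locking: 3.5
    osc_period: 100
paperlike_special:
  set: special
  n_neurons: 10
  n_repetitions: 8
  seed: 2013
  timeline:
    movement_duration_mean: 407
    movement_duration_sd: 192
  tuning:
    baseline_rate_mean: 12
    baseline_rate_shape: 4
    peak_rate_mean: 65
    peak_rate_shape: 10
    within_group_share: [0.15, 0.45]
    across_group_share: [0.0, 0.2]
    onset_latency_mean: -150
    onset_latency_sd: 120
    onset_latency_range: [-400, 150]
    rise_time_range: [30, 50]
    rate_jitter_sd: 0
    osc_locking: 3.5
    osc_period: 100
"null":
  set: original
  n_neurons: 36
  n_repetitions: 8
  seed: 2014
  tuning:
    baseline_rate_mean: 6
    modulation_gain: 0
    rate_jitter_sd: 0
    osc_locking: 0
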