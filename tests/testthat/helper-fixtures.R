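# Shared small fixtures, generated in code.

# tuning with strong, sharp, well-separated responses (no rhythm, no drift)
sharp_tuning <- function(onset = -400, peak = 80, baseline = 3) {
  tuning_spec(baseline_rate_mean = baseline, baseline_rate_shape = 8,
              peak_rate_mean = peak, peak_rate_shape = 20,
              within_group_share = c(0, 0.1), across_group_share = c(0, 0.1),
              onset_latency_mean = onset, onset_latency_sd = 0.001,
              onset_latency_range = c(onset, onset),
              rise_time_range = c(15, 25),
              rate_jitter_sd = 0, osc_locking = 0)
}

untuned <- function(baseline = 6) {
  tuning_spec(baseline_rate_mean = baseline, modulation_gain = 0,
              rate_jitter_sd = 0, osc_locking = 0)
}

small_pop <- function(n_neurons = 8, n_repetitions = 4, tuning = sharp_tuning(),
                      seed = 42, set = "original") {
  generate_population(grip_taxonomy(set), task_timeline(), n_neurons,
                      n_repetitions, tuning, seed)
}

# brute-force windowed rates: double loop over spikes x windows
oracle_rates <- function(spikes, grid) {
  vapply(seq_len(nrow(grid)), function(w) {
    n <- 0L
    for (s in spikes)
      if (s >= grid$start[w] && s < grid$end[w]) n <- n + 1L
    n / (attr(grid, "bin_width") / 1000)
  }, numeric(1))
}
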