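test_that("population has one trial per (neuron, object, repetition)", {
  pop <- small_pop(n_neurons = 5, n_repetitions = 3)
  expect_equal(nrow(pop$trials), 5 * 6 * 3)
  expect_false(anyDuplicated(pop$trials$trial_id) > 0)
  # the full-scale protocol: 36 neurons x 6 objects x 8 repetitions = 1728
  tab <- table(pop$trials$neuron_id, pop$trials$object_id)
  expect_true(all(tab == 3))
})

test_that("identical seeds reproduce the dataset byte for byte", {
  a <- small_pop(seed = 9)
  b <- small_pop(seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$trials, b$trials)
  c <- small_pop(seed = 10)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("pairing is a bijection between repetitions per neuron and object", {
  pop <- small_pop(n_neurons = 6, n_repetitions = 4)
  by_cell <- split(pop$trials$pseudo_trial,
                   interaction(pop$trials$neuron_id, pop$trials$object_id))
  for (p in by_cell) expect_length(unique(p), 4L)
  # pseudo-trial ids partition by object
  obj_of_pseudo <- tapply(pop$trials$object_id, pop$trials$pseudo_trial, unique)
  expect_true(all(lengths(obj_of_pseudo) == 1L))
})

test_that("spikes respect the epoch, ordering, and zero-rate silence", {
  pop <- small_pop()
  tl <- pop$timeline
  expect_true(all(pop$spikes$spike_time_ms >= tl$epoch[1] &
                  pop$spikes$spike_time_ms <= tl$epoch[2]))
  srt <- tapply(pop$spikes$spike_time_ms, pop$spikes$trial_id, is.unsorted)
  expect_false(any(srt))

  # zero baseline + onset at 0: nothing can fire before key release
  quiet <- tuning_spec(baseline_rate_mean = 0, peak_rate_mean = 50,
                       onset_latency_mean = 0, onset_latency_sd = 0.001,
                       onset_latency_range = c(0, 0),
                       rise_time_range = c(10, 20),
                       rate_jitter_sd = 0, osc_locking = 0)
  pop0 <- generate_population(grip_taxonomy("original"), task_timeline(),
                              3, 3, quiet, seed = 1)
  expect_true(all(pop0$spikes$spike_time_ms >= 0))
})

test_that("empirical rates recover the programmed profile", {
  # one neuron, many repetitions: baseline and plateau windows should match
  # the programmed rates within 3 standard errors
  tun <- sharp_tuning(onset = -400, peak = 60, baseline = 10)
  pop <- generate_population(grip_taxonomy("original"), task_timeline(),
                             1, 200, tun, seed = 5)
  base_rate <- pop$tuning$baseline_rate[1]
  o <- pop$tuning$preferred_object[1]
  plateau <- pop$tuning$plateau_rates[1, o]
  tr <- pop$trials[pop$trials$object_id == o, ]
  spk <- pop$spikes[pop$spikes$trial_id %in% tr$trial_id, ]
  count_in <- function(a, b) sum(spk$spike_time_ms >= a & spk$spike_time_ms < b)
  # baseline interval [-1800, -500): before every onset
  n1 <- count_in(-1800, -500)
  lam1 <- base_rate * 1.3 * 200
  expect_lt(abs(n1 - lam1), 3 * sqrt(lam1))
  # plateau interval [-300, 0): after onset + rise, before any movement end
  n2 <- count_in(-300, 0)
  lam2 <- plateau * 0.3 * 200
  expect_lt(abs(n2 - lam2), 3 * sqrt(lam2))
})

test_that("untuned neurons carry no grip information", {
  pop <- small_pop(n_neurons = 6, n_repetitions = 8, tuning = untuned(),
                   seed = 3)
  # per-object mean spike counts differ only by Poisson noise
  counts <- tapply(pop$spikes$trial_id, pop$spikes$trial_id, length)
  per_trial <- data.frame(trial_id = names(counts), n = as.vector(counts))
  merged <- merge(pop$trials, per_trial, all.x = TRUE)
  merged$n[is.na(merged$n)] <- 0
  fit <- stats::kruskal.test(merged$n, factor(merged$object_id))
  expect_gt(fit$p.value, 0.001)
  # rates identical across grips by construction
  expect_true(all(apply(pop$tuning$plateau_rates, 1,
                        function(r) diff(range(r)) == 0)))
})

test_that("parameter errors name the offending field", {
  tax <- grip_taxonomy("original")
  tl <- task_timeline()
  expect_error(tuning_spec(peak_rate_mean = -5), "peak_rate_mean")
  expect_error(tuning_spec(rise_time_range = c(0, 10)), "rise_time_range")
  expect_error(task_timeline(movement_duration_mean = -1),
               "movement_duration_mean")
  expect_error(generate_population(tax, tl, 0, 8, tuning_spec(), 1),
               "n_neurons")
  expect_error(generate_population(tax, tl, 4, 1, tuning_spec(), 1),
               "n_repetitions")
})

test_that("reference scenarios ship the frozen definitions", {
  sc <- reference_scenarios()
  expect_true(all(c("separable", "paperlike", "null") %in% names(sc)))
  expect_equal(sc$paperlike$n_neurons, 36)
  expect_equal(sc$paperlike$n_repetitions, 8)
  expect_equal(sc$paperlike$set, "original")
  expect_equal(sc$paperlike_special$n_neurons, 10)
  expect_s3_class(sc$null$tuning, "tuning_spec")
  expect_equal(sc$null$tuning$modulation_gain, 0)
  expect_error(generate_scenario("nope"), "unknown scenario")
  # scenario generation is reproducible
  a <- generate_scenario("null")
  b <- generate_scenario("null")
  expect_identical(a$spikes, b$spikes)
})
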