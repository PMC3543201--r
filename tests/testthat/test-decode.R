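test_that("window labels separate baseline from grip at the trial boundary", {
  pop <- small_pop(n_neurons = 8, n_repetitions = 4)
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  expect_equal(dim(lab$labels), c(24, 191))
  # every window has exactly one label; grip label matches the trial's object
  for (p in c(1, 10, 24)) {
    labs <- unique(lab$labels[p, ])
    expect_true(all(labs %in% c("baseline", f$trial_info$grip_label[p])))
  }
  # windows ending at or before the boundary are baseline
  for (p in seq_len(24)) {
    b <- lab$boundaries$boundary_ms[p]
    expect_true(all(lab$labels[p, f$grid$end <= b] == "baseline"))
    # execution windows (after key release) always carry the grip
    expect_true(all(lab$labels[p, f$grid$end > 0] ==
                    f$trial_info$grip_label[p]))
  }
  # k = 4 merges the first three objects
  lab4 <- label_windows(f, k = 4)
  expect_equal(sort(unique(as.character(lab4$labels))),
               sort(c("baseline", "g123", "g4", "g5", "g6")))
})

test_that("clean-step trials label grip windows exactly past the onset", {
  # sharp population-wide step at -400: every object drives every neuron, so
  # the trial series jumps far above threshold and the boundary lands within
  # one bin of the step
  step_tuning <- tuning_spec(
    baseline_rate_mean = 3, baseline_rate_shape = 8,
    peak_rate_mean = 100, peak_rate_shape = 20,
    within_group_share = c(0.6, 0.9), across_group_share = c(0.6, 0.9),
    onset_latency_mean = -400, onset_latency_sd = 0.001,
    onset_latency_range = c(-400, -400), rise_time_range = c(15, 25),
    rate_jitter_sd = 0, osc_locking = 0)
  pop <- small_pop(n_neurons = 12, n_repetitions = 4, tuning = step_tuning,
                   seed = 2)
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  expect_true(all(lab$boundaries$source == "trial"))
  # the vast majority of boundaries sit at the step (rare pre-step noise
  # runs may fire earlier; sub-threshold windows there stay baseline)
  expect_gte(mean(abs(lab$boundaries$boundary_ms - (-400)) <= 100), 0.9)
  n_grip <- rowSums(lab$labels != "baseline")
  expected <- sum(f$grid$end > -400)
  expect_lte(max(abs(n_grip - expected)), 12)
  expect_lte(median(abs(n_grip - expected)), 3)
})

test_that("splits are stratified, disjoint, seeded, and trial-wise", {
  info <- data.frame(pseudo_trial = 1:48, object_id = rep(1:6, each = 8))
  sp <- split_trials(info, 0.25, n_repeats = 20, seed = 4)
  for (r in sp$repeats) {
    expect_length(r$train, 12L)  # 2 per object
    expect_length(r$test, 36L)   # 6 per object
    expect_length(intersect(r$train, r$test), 0L)
    expect_setequal(c(r$train, r$test), 1:48)
    expect_true(all(table(info$object_id[match(r$train, info$pseudo_trial)]) == 2))
  }
  sp2 <- split_trials(info, 0.25, n_repeats = 20, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_trials(info, 1.0), "train_fraction")
  expect_error(split_trials(info, 0.9999), "test trials")
  expect_error(split_trials(data.frame(pseudo_trial = 1:6,
                                       object_id = 1:6), 0.25),
               "fewer than 2")
})

test_that("direct and hierarchical schemes decode a separable population", {
  pop <- generate_scenario("separable")
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  sp <- split_trials(f$trial_info, n_repeats = 2, seed = 5)
  rd <- run_decoding(f, lab, sp, "direct", seed = 5)
  rh <- run_decoding(f, lab, sp, "hierarchical", seed = 5)
  expect_equal(rd$n_classes, 7L)      # baseline + six grips
  expect_gt(rd$rr_mean, 97)
  expect_gt(rh$rr_mean, 97)
  # the two schemes agree on essentially every test window
  m1 <- withr::with_seed(6, train_direct(f, lab, sp$repeats[[1]]$train))
  m2 <- withr::with_seed(6, train_hierarchical(f, lab, sp$repeats[[1]]$train))
  p1 <- predict_continuous(m1, f, sp$repeats[[1]]$test)
  p2 <- predict_continuous(m2, f, sp$repeats[[1]]$test)
  expect_gt(mean(p1 == p2), 0.99)
  # 4-grip mode: stage 2 and the direct machine see 4 grip classes
  lab4 <- label_windows(f, k = 4)
  m4 <- withr::with_seed(6, train_hierarchical(f, lab4, sp$repeats[[1]]$train))
  expect_length(m4$stage2$levels, 4L)  # e1071 stores class levels in the model
  r4 <- run_decoding(f, lab4, sp, "direct", seed = 5)
  expect_equal(r4$n_classes, 5L)
})

test_that("continuous predictions have one label per test window", {
  pop <- small_pop(n_neurons = 6, n_repetitions = 4)
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  sp <- split_trials(f$trial_info, n_repeats = 1, seed = 1)
  m <- withr::with_seed(1, train_direct(f, lab, sp$repeats[[1]]$train))
  pred <- predict_continuous(m, f, sp$repeats[[1]]$test)
  expect_equal(dim(pred), c(18L, 191L))
  expect_equal(rownames(pred), as.character(sort(sp$repeats[[1]]$test)))
  expect_true(all(pred %in% c("baseline", paste0("g", 1:6))))
  # bin-width mismatch is a contract error
  f50 <- assemble_features(pop, make_window_grid(50))
  expect_error(predict_continuous(m, f50), "bin-width mismatch")
})

test_that("recognition ratio counts correct grips in the requested scope", {
  truth <- c("baseline", "baseline", "g1", "g1", "g2", "g3")
  pred  <- c("baseline", "g1",       "g1", "g2", "g2", "g3")
  # 3 of 4 grip-true windows correct
  expect_equal(recognition_ratio(pred, truth, "grip"), 75)
  expect_equal(recognition_ratio(pred, truth, "all"), 100 * 4 / 6)
  expect_equal(recognition_ratio(truth, truth), 100)
  allwrong <- c("g9", "g9", "g2", "g2", "g1", "g1")
  expect_equal(recognition_ratio(allwrong, truth, "grip"), 0)
  expect_error(recognition_ratio("baseline", "baseline", "grip"),
               "no grip-labeled")
})

test_that("training fails informatively when a class is absent", {
  pop <- small_pop(n_neurons = 6, n_repetitions = 4)
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  # drop object 6 from training
  train <- f$trial_info$pseudo_trial[f$trial_info$object_id != 6][1:10]
  expect_error(withr::with_seed(1, train_direct(f, lab, train)), "g6")
  expect_error(withr::with_seed(1, train_hierarchical(f, lab, train)), "g6")
})
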