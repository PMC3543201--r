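# brute-force Friedman statistic: rank within each block (average ranks),
# tie-corrected chi-square on the column rank sums
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  ties <- apply(r, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (den == 0) return(0)      # every block fully tied
  num / den
}

# brute-force Kruskal-Wallis H with tie correction
oracle_kw <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(v) sum(v)^2 / length(v))) - 3 * (n + 1)
  tab <- table(x)
  corr <- 1 - sum(tab^3 - tab) / (n^3 - n)
  if (corr == 0) return(0)     # all observations identical
  h / corr
}

test_that("Friedman statistic equals the rank oracle on small instances", {
  # identical conditions: statistic 0, p = 1
  f0 <- friedman_rr(matrix(1, 4, 3) * c(1, 2, 3, 4))
  expect_equal(unname(f0$statistic), 0)
  expect_equal(f0$p.value, 1)

  # hand-built 3 x 4 instance with known ranks
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3)) * 10
  expect_equal(unname(friedman_rr(m)$statistic), oracle_friedman(m))

  # all instances with <= 8 observations (blocks x conditions combinations)
  withr::with_seed(13, {
    for (dims in list(c(2, 2), c(2, 3), c(2, 4), c(3, 2), c(4, 2))) {
      for (i in 1:20) {
        mm <- matrix(sample(1:4, prod(dims), replace = TRUE), dims[1])
        expect_equal(unname(friedman_rr(mm)$statistic), oracle_friedman(mm))
      }
    }
  })

  # one condition uniformly best across >= 7 blocks is significant at 0.01
  mbest <- cbind(stats::runif(8, 90, 95), stats::runif(8, 80, 85),
                 stats::runif(8, 80, 85))
  expect_lte(friedman_rr(mbest)$p.value, 0.01)
  expect_error(friedman_rr(matrix(1:3, 1)), "blocks")
  expect_error(friedman_rr(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("Friedman chi-square p agrees with a within-block permutation oracle", {
  withr::with_seed(14, {
    m <- matrix(stats::rnorm(8 * 3, mean = rep(c(0, 0.6, 1), each = 8)), 8)
    obs <- unname(friedman_rr(m)$statistic)
    perm <- replicate(2000, {
      mp <- t(apply(m, 1, sample))
      oracle_friedman(mp)
    })
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(friedman_rr(m)$p.value - p_perm), 0.05)
  })
})

test_that("Kruskal-Wallis H equals the rank oracle and its p the permutation p", {
  # identical groups: H = 0
  expect_equal(unname(kruskal_rr(rep(1, 9), rep(1:3, 3))$statistic), 0)
  # {1,2,3} vs {4,5,6}: ranks 1..6, plug into the H formula by hand
  x <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b"), each = 3)
  expect_equal(unname(kruskal_rr(x, g)$statistic), oracle_kw(x, g))
  expect_equal(unname(kruskal_rr(x, g)$statistic),
               12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7)

  withr::with_seed(15, {
    # oracle identity on instances with <= 8 observations, with ties
    for (i in 1:40) {
      n <- sample(4:8, 1)
      x <- sample(1:4, n, replace = TRUE)
      g <- sample(rep(1:2, length.out = n))
      if (min(table(g)) < 2) next
      expect_equal(unname(kruskal_rr(x, g)$statistic), oracle_kw(x, g))
    }
    # chi-square p vs Monte-Carlo permutation p at n >= 10 per group
    x <- c(stats::rnorm(12, 0), stats::rnorm(12, 0.8), stats::rnorm(12, 1.2))
    g <- rep(1:3, each = 12)
    obs <- unname(kruskal_rr(x, g)$statistic)
    perm <- replicate(4000, oracle_kw(x, sample(g)))
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(kruskal_rr(x, g)$p.value - p_perm), 0.02)
  })
  expect_error(kruskal_rr(1:4, c(1, 1, 1, 1)), "groups")
  expect_error(kruskal_rr(1:4, c(1, 1, 2, 3)), "2 samples")
})

test_that("bin-width sweep runs the chain per condition with shared splits", {
  pop <- small_pop(n_neurons = 8, n_repetitions = 4, seed = 17)
  sw <- sweep_bin_widths(pop, bin_widths = c(50, 100),
                         schemes = c("direct", "hierarchical"), ks = 6,
                         n_repeats = 3, seed = 2)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4L)
  expect_setequal(sw$bin_width, c(50, 100))
  expect_true(all(sw$rr_mean >= 0 & sw$rr_mean <= 100))
  rr <- attr(sw, "rr")
  expect_equal(dim(rr), c(3L, 4L))
  # reproducible bit for bit under the same seed
  sw2 <- sweep_bin_widths(pop, bin_widths = c(50, 100),
                          schemes = c("direct", "hierarchical"), ks = 6,
                          n_repeats = 3, seed = 2)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(sweep_bin_widths(pop, numeric(0)), "bin_widths")
})

test_that("figures render from pipeline components", {
  pop <- small_pop(n_neurons = 6, n_repetitions = 4)
  f <- assemble_features(pop, make_window_grid(100))
  lab <- label_windows(f)
  sp <- split_trials(f$trial_info, n_repeats = 2, seed = 1)
  rep <- run_decoding(f, lab, sp, "direct", seed = 1)
  sw <- sweep_bin_widths(pop, bin_widths = c(50, 100), n_repeats = 2, seed = 1)
  dir <- withr::local_tempdir()
  paths <- render_outputs(dir, features = f, pop = pop, sweep = sw,
                          report = rep)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  # skipped panels are messaged, not errors
  expect_message(render_outputs(dir, features = f, pop = pop),
                 "skipping")
})
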