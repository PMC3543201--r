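#' Tuning-distribution specification for simulated grasping neurons
#'
#' Describes the population distribution from which per-neuron tuning is
#' drawn.  Each simulated neuron is a grasp-modulated motor unit: it fires at
#' a baseline rate during object presentation, then ramps linearly to an
#' object-dependent plateau rate starting at its response-onset latency and
#' holds it until the end of the movement (ramp-and-hold profile).  A neuron
#' has one preferred object at the full peak rate; other objects receive a
#' fraction of the modulation depth.  Objects that share grip features (the
#' merged triplet of the taxonomy) receive correlated, higher fractions, so
#' that confusions concentrate among them as in real premotor populations.
#'
#' Rates are in spikes/s, times in ms relative to key release.
#'
#' @param baseline_rate_mean Mean baseline rate (gamma-distributed across
#'   neurons).
#' @param baseline_rate_shape Gamma shape of the baseline-rate distribution.
#' @param peak_rate_mean Mean peak (preferred-object plateau) rate.
#' @param peak_rate_shape Gamma shape of the peak-rate distribution.
#' @param within_group_share Length-2 range of the modulation fraction given
#'   to non-preferred objects in the same merged grip group as the preferred
#'   object.
#' @param across_group_share Length-2 range of the modulation fraction for
#'   objects outside the preferred object's merged group.
#' @param onset_latency_mean,onset_latency_sd Mean/SD of the response-onset
#'   latency (ms, typically negative: premotor activity precedes movement).
#' @param onset_latency_range Hard clip range for latencies.
#' @param rise_time_range Range of the linear ramp duration (ms).
#' @param modulation_gain Global multiplier on (peak - baseline) modulation
#'   depth; 0 yields untuned neurons firing at baseline throughout.
#' @param rate_jitter_sd Stationary SD of the slow multiplicative log-gain
#'   fluctuation applied to each trial's rate profile (0 disables it).
#'   Cortical firing is overdispersed relative to a homogeneous Poisson
#'   process; this excitability fluctuation reproduces that Fano factor > 1
#'   and, with it, a realistically wide baseline band for the onset
#'   threshold.
#' @param rate_jitter_tau Correlation time of the log-gain fluctuation (ms).
#' @param osc_locking Concentration (von Mises kappa, >= 0) of rhythmic
#'   phase-locking of the firing rate, with a random phase per trial.  Motor
#'   and premotor spiking is entrained to low-frequency population rhythms:
#'   the rate is multiplied by the mean-one periodic gain
#'   `exp(kappa * cos(2*pi*t/P + phi)) / I0(kappa)`.  Because the phase is
#'   not locked to task events, analysis windows shorter than one cycle see
#'   the modulation as irreducible rate noise, while windows spanning whole
#'   cycles integrate it away exactly; kappa sets the locking depth (0 =
#'   none; small kappa approaches a sinusoidal modulation of amplitude
#'   kappa).
#' @param osc_period Oscillation period in ms (default 100, i.e. 10 Hz).
#' @param osc_movement_suppression Fraction (0-1) by which the locking depth
#'   is reduced once the neuron's grasp response begins (event-related
#'   desynchronization: the rhythm is prominent during postural holding /
#'   object presentation and collapses at movement initiation).
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(baseline_rate_mean = 6,
                        baseline_rate_shape = 4,
                        peak_rate_mean = 45,
                        peak_rate_shape = 6,
                        within_group_share = c(0.55, 0.9),
                        across_group_share = c(0.0, 0.4),
                        onset_latency_mean = -300,
                        onset_latency_sd = 70,
                        onset_latency_range = c(-700, 100),
                        rise_time_range = c(60, 140),
                        modulation_gain = 1,
                        rate_jitter_sd = 0.4,
                        rate_jitter_tau = 200,
                        osc_locking = 0,
                        osc_period = 100,
                        osc_movement_suppression = 0) {
  check_scalar_number(baseline_rate_mean, "baseline_rate_mean")
  if (baseline_rate_mean < 0) stop_param("baseline_rate_mean", "must be >= 0")
  check_scalar_number(baseline_rate_shape, "baseline_rate_shape", positive = TRUE)
  check_scalar_number(peak_rate_mean, "peak_rate_mean", positive = TRUE)
  check_scalar_number(peak_rate_shape, "peak_rate_shape", positive = TRUE)
  check_scalar_number(modulation_gain, "modulation_gain")
  if (modulation_gain < 0) stop_param("modulation_gain", "must be >= 0")
  if (length(rise_time_range) != 2L || any(rise_time_range <= 0))
    stop_param("rise_time_range", "must be two positive durations (ms)")
  check_scalar_number(rate_jitter_sd, "rate_jitter_sd")
  if (rate_jitter_sd < 0) stop_param("rate_jitter_sd", "must be >= 0")
  check_scalar_number(rate_jitter_tau, "rate_jitter_tau", positive = TRUE)
  check_scalar_number(osc_locking, "osc_locking")
  if (osc_locking < 0) stop_param("osc_locking", "must be >= 0")
  check_scalar_number(osc_period, "osc_period", positive = TRUE)
  check_scalar_number(osc_movement_suppression, "osc_movement_suppression")
  if (osc_movement_suppression < 0 || osc_movement_suppression > 1)
    stop_param("osc_movement_suppression", "must be in [0, 1]")
  structure(
    list(baseline_rate_mean = baseline_rate_mean,
         baseline_rate_shape = baseline_rate_shape,
         peak_rate_mean = peak_rate_mean,
         peak_rate_shape = peak_rate_shape,
         within_group_share = as.numeric(within_group_share),
         across_group_share = as.numeric(across_group_share),
         onset_latency_mean = onset_latency_mean,
         onset_latency_sd = onset_latency_sd,
         onset_latency_range = as.numeric(onset_latency_range),
         rise_time_range = as.numeric(rise_time_range),
         modulation_gain = modulation_gain,
         rate_jitter_sd = rate_jitter_sd,
         rate_jitter_tau = rate_jitter_tau,
         osc_locking = osc_locking,
         osc_period = osc_period,
         osc_movement_suppression = osc_movement_suppression),
    class = "tuning_spec")
}

# draw per-neuron tuning from a tuning_spec; uses the current RNG stream
draw_tuning <- function(spec, taxonomy, n_neurons) {
  g <- function(mean, shape) {
    if (mean == 0) rep(0, n_neurons)
    else stats::rgamma(n_neurons, shape = shape, scale = mean / shape)
  }
  baseline <- g(spec$baseline_rate_mean, spec$baseline_rate_shape)
  peak <- g(spec$peak_rate_mean, spec$peak_rate_shape)
  preferred <- sample.int(6L, n_neurons, replace = TRUE)
  merged <- taxonomy$merged_labels
  share <- matrix(0, n_neurons, 6L)
  for (i in seq_len(n_neurons)) {
    same_group <- merged == merged[preferred[i]]
    share[i, ] <- stats::runif(6L, spec$across_group_share[1],
                               spec$across_group_share[2])
    share[i, same_group] <- stats::runif(sum(same_group),
                                         spec$within_group_share[1],
                                         spec$within_group_share[2])
    share[i, preferred[i]] <- 1
  }
  depth <- pmax(peak - baseline, 0) * spec$modulation_gain
  rates <- baseline + share * depth              # n_neurons x 6 plateau rates
  latency <- pmin(pmax(stats::rnorm(n_neurons, spec$onset_latency_mean,
                                    spec$onset_latency_sd),
                       spec$onset_latency_range[1]),
                  spec$onset_latency_range[2])
  rise <- stats::runif(n_neurons, spec$rise_time_range[1],
                       spec$rise_time_range[2])
  list(baseline_rate = baseline, preferred_object = preferred,
       plateau_rates = rates, onset_latency = latency, rise_time = rise)
}

# ramp-and-hold rate profile (spikes/s) evaluated at times t (ms)
rate_profile <- function(t, baseline, plateau, onset, rise, movement_end) {
  r <- rep(baseline, length(t))
  ramp <- t >= onset & t < onset + rise
  r[ramp] <- baseline + (plateau - baseline) * (t[ramp] - onset) / rise
  hold <- t >= onset + rise & t <= movement_end
  r[hold] <- plateau
  r[t > movement_end] <- baseline
  r
}

# slow excitability fluctuation: mean-one multiplicative gain exp(eta(t))
# with eta an Ornstein-Uhlenbeck process of stationary SD `sd` and
# correlation time `tau`, sampled on a `dt`-ms grid
ou_gain <- function(n_steps, sd, tau, dt = 10) {
  if (sd <= 0) return(rep(1, n_steps))
  a <- exp(-dt / tau)
  eta <- numeric(n_steps)
  eta[1] <- stats::rnorm(1L, 0, sd)
  innov <- stats::rnorm(n_steps - 1L, 0, sd * sqrt(1 - a^2))
  for (k in 2:n_steps) eta[k] <- a * eta[k - 1L] + innov[k - 1L]
  exp(eta - sd^2 / 2)
}

# inhomogeneous-Poisson spike times over the epoch by thinning, with the
# rate held piecewise-constant over 1 ms bins and modulated by the slow
# excitability gain (piecewise-constant over 10 ms)
draw_spikes <- function(baseline, plateau, onset, rise, movement_end, epoch,
                        jitter_sd = 0, jitter_tau = 200,
                        osc_locking = 0, osc_period = 100,
                        osc_suppression = 0) {
  rmax <- max(baseline, plateau)
  if (rmax <= 0) return(numeric(0))
  dur <- epoch[2] - epoch[1]
  gain <- ou_gain(ceiling(dur / 10), jitter_sd, jitter_tau)
  osc_max <- if (osc_locking > 0)
    exp(osc_locking) / besselI(osc_locking, 0) else 1
  gmax <- max(gain) * osc_max
  phase <- stats::runif(1L, 0, 2 * pi)
  n <- stats::rpois(1L, rmax * gmax * dur / 1000)
  if (n == 0L) return(numeric(0))
  t <- stats::runif(n, epoch[1], epoch[2])
  tq <- epoch[1] + floor(t - epoch[1])    # 1 ms resolution for the rate
  g <- gain[pmin(floor((t - epoch[1]) / 10) + 1L, length(gain))]
  if (osc_locking > 0) {
    kap <- ifelse(tq < onset, osc_locking, osc_locking * (1 - osc_suppression))
    g <- g * exp(kap * cos(2 * pi * tq / osc_period + phase)) / besselI(kap, 0)
  }
  rate <- g * rate_profile(tq, baseline, plateau, onset, rise, movement_end)
  keep <- stats::runif(n) < rate / (rmax * gmax)
  sort(t[keep])
}

#' Simulate a pseudo-population of grip-tuned neurons
#'
#' Generates event-aligned spike trains for `n_neurons` grasp-modulated
#' neurons, each "recorded" in `n_repetitions` trials per object of the
#' six-object set.  Spikes are drawn from an inhomogeneous Poisson process
#' (thinning at 1 ms rate resolution) whose rate follows a ramp-and-hold
#' profile: baseline before the neuron's onset latency, linear ramp of
#' duration `rise_time` to the object-dependent plateau, hold until the
#' trial's movement end.  Movement duration is drawn per trial from the
#' timeline's truncated normal.
#'
#' Neurons were recorded one at a time in the experiments this emulates, so
#' the population is assembled into *pseudo-trials*: for each object, the
#' repetition indices of every neuron are randomly permuted (seeded) and the
#' r-th permuted repetition of all neurons is paired into pseudo-trial r.
#'
#' @param taxonomy A [grip_taxonomy()].
#' @param timeline A [task_timeline()].
#' @param n_neurons Number of neurons (>= 1).
#' @param n_repetitions Repetitions per object (>= 2); the task used 8.
#' @param tuning A [tuning_spec()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `grip_population`: list with `taxonomy`,
#'   `timeline`, `tuning` (per-neuron draws), `trials` (data frame with one
#'   row per neuron x object x repetition: `trial_id`, `neuron_id`,
#'   `object_id`, `grip_label`, `rep_index`, `pseudo_trial`,
#'   `movement_end_ms`), `spikes` (data frame `trial_id`, `spike_time_ms`),
#'   and the generation parameters.
#' @examples
#' pop <- generate_population(grip_taxonomy("original"), task_timeline(),
#'                            n_neurons = 4, n_repetitions = 3,
#'                            tuning = tuning_spec(), seed = 1)
#' nrow(pop$trials)  # 4 * 6 * 3
#' @export
generate_population <- function(taxonomy, timeline, n_neurons, n_repetitions,
                                tuning = tuning_spec(), seed = 1L) {
  if (!inherits(taxonomy, "grip_taxonomy"))
    stop_param("taxonomy", "must be a grip_taxonomy")
  if (!inherits(timeline, "task_timeline"))
    stop_param("timeline", "must be a task_timeline")
  if (!inherits(tuning, "tuning_spec"))
    stop_param("tuning", "must be a tuning_spec")
  check_scalar_number(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  check_scalar_number(n_repetitions, "n_repetitions", positive = TRUE,
                      integerish = TRUE)
  if (n_repetitions < 2) stop_param("n_repetitions", "must be >= 2")
  check_scalar_number(seed, "seed", integerish = TRUE)

  with_seed(seed, {
    tun <- draw_tuning(tuning, taxonomy, n_neurons)

    # pairing: per neuron and object, a random permutation of repetitions
    pairing <- array(0L, dim = c(n_neurons, 6L, n_repetitions))
    for (i in seq_len(n_neurons))
      for (o in 1:6)
        pairing[i, o, ] <- sample.int(n_repetitions)

    trials <- expand.grid(rep_index = seq_len(n_repetitions),
                          object_id = 1:6,
                          neuron_id = seq_len(n_neurons),
                          KEEP.OUT.ATTRS = FALSE)
    trials <- trials[, c("neuron_id", "object_id", "rep_index")]
    n_tr <- nrow(trials)
    trials$trial_id <- sprintf("n%03d_o%d_r%02d", trials$neuron_id,
                               trials$object_id, trials$rep_index)
    trials$grip_label <- taxonomy$grip_labels[trials$object_id]
    # pseudo-trial that this actual trial is paired into
    prep <- mapply(function(i, o, r) pairing[i, o, r],
                   trials$neuron_id, trials$object_id, trials$rep_index)
    trials$pseudo_trial <- (trials$object_id - 1L) * n_repetitions + prep
    trials$movement_end_ms <- rnorm_trunc(n_tr, timeline$movement_duration_mean,
                                          timeline$movement_duration_sd, 50)

    spk <- vector("list", n_tr)
    for (j in seq_len(n_tr)) {
      i <- trials$neuron_id[j]
      o <- trials$object_id[j]
      spk[[j]] <- draw_spikes(tun$baseline_rate[i], tun$plateau_rates[i, o],
                              tun$onset_latency[i], tun$rise_time[i],
                              trials$movement_end_ms[j], timeline$epoch,
                              tuning$rate_jitter_sd, tuning$rate_jitter_tau,
                              tuning$osc_locking, tuning$osc_period,
                              tuning$osc_movement_suppression)
    }
    ns <- lengths(spk)
    spikes <- data.frame(trial_id = rep(trials$trial_id, ns),
                         spike_time_ms = unlist(spk))
    rownames(trials) <- rownames(spikes) <- NULL

    structure(
      list(taxonomy = taxonomy, timeline = timeline, tuning = tun,
           trials = trials, spikes = spikes,
           n_neurons = as.integer(n_neurons),
           n_repetitions = as.integer(n_repetitions),
           seed = as.integer(seed)),
      class = "grip_population")
  })
}

#' @export
print.grip_population <- function(x, ...) {
  cat(sprintf("<grip_population> %s set: %d neurons, %d objects x %d repetitions (%d trials, %d spikes)\n",
              x$taxonomy$set_name, x$n_neurons, 6L, x$n_repetitions,
              nrow(x$trials), nrow(x$spikes)))
  invisible(x)
}
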