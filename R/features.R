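#' Sliding analysis-window grid
#'
#' Enumerates the analysis windows of width `bin_width` slid over the epoch
#' with the given step.  Windows are half-open `[start, end)` so a spike on a
#' shared boundary is counted once, in the later window.  The number of
#' windows is `floor((epoch length - bin_width) / step) + 1`.
#'
#' @param bin_width Window width in ms (the task analyses used 25-200 ms).
#' @param step Slide step in ms (default 10).
#' @param epoch Length-2 epoch in ms (default `c(-1800, 200)`).
#' @return A `window_grid`: data frame with columns `start`, `end` and
#'   attributes `bin_width`, `step`, `epoch`.
#' @examples
#' nrow(make_window_grid(100))  # 191 windows over [-1800, 200]
#' @export
make_window_grid <- function(bin_width, step = 10, epoch = c(-1800, 200)) {
  check_scalar_number(bin_width, "bin_width", positive = TRUE)
  check_scalar_number(step, "step", positive = TRUE)
  if (length(epoch) != 2L || epoch[1] >= epoch[2])
    stop_param("epoch", "must be an increasing (start, end) pair")
  len <- epoch[2] - epoch[1]
  if (bin_width > len)
    stop_param("bin_width", sprintf("exceeds the epoch length (%g ms)", len))
  starts <- seq(epoch[1], epoch[2] - bin_width, by = step)
  grid <- data.frame(start = starts, end = starts + bin_width)
  attr(grid, "bin_width") <- bin_width
  attr(grid, "step") <- step
  attr(grid, "epoch") <- as.numeric(epoch)
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Windowed firing rates of one spike train
#'
#' Counts spikes in each half-open window `[start, end)` of the grid and
#' divides by the window width in seconds.  Spikes outside the epoch never
#' contribute (no window extends beyond it).
#'
#' @param spike_times Sorted numeric vector of spike times (ms).
#' @param grid A [make_window_grid()] grid.
#' @return Numeric vector of rates (spikes/s), one per window.
#' @export
windowed_rates <- function(spike_times, grid) {
  if (is.unsorted(spike_times))
    stop("spike times must be sorted in increasing order", call. = FALSE)
  # half-open count: #(v < end) - #(v < start)
  lt <- function(x) findInterval(x, spike_times, left.open = TRUE)
  counts <- lt(grid$end) - lt(grid$start)
  counts / (attr(grid, "bin_width") / 1000)
}

#' Normalize one neuron's windowed rates by its maximum
#'
#' Divides every rate of a neuron (all trials, all windows, one bin width) by
#' that neuron's maximum windowed rate over all trials, so normalized firing
#' rates (nFR) lie in [0, 1] with the maximizing window mapping to exactly 1.
#'
#' @param rates Numeric vector, matrix or array of one neuron's raw windowed
#'   rates across all its trials.
#' @return List with `values` (same shape, in [0, 1]) and `constant` (the
#'   per-neuron maximum rate used).  A neuron with no spikes anywhere has an
#'   undefined normalization; an error is thrown (population assembly drops
#'   such neurons with a warning instead).
#' @export
normalize_rates <- function(rates) {
  m <- max(rates)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize an all-zero neuron (no spikes in any window)",
         call. = FALSE)
  list(values = rates / m, constant = m)
}

#' Assemble the pseudo-population feature matrix
#'
#' Computes windowed rates for every trial of every neuron on the grid,
#' normalizes each neuron by its own maximum rate (per bin width, across all
#' of its trials and windows), and pairs the neurons' repetitions into
#' pseudo-trials using the dataset's pairing.  The feature vector of
#' pseudo-trial p at window w is the concatenation of the paired neurons' nFR
#' at w.  Neurons with no spikes at all are dropped with a warning (their
#' normalization is undefined).
#'
#' @param pop A [generate_population()] dataset.
#' @param grid A [make_window_grid()] grid.
#' @return A `grip_features` object: list with `values` (array
#'   pseudo-trial x window x neuron, in [0, 1]), `grid`, `trial_info` (data
#'   frame `pseudo_trial`, `object_id`, `grip_label`), `neuron_ids` (kept
#'   neurons), `norm_constants` and `dropped_neurons`.
#' @export
assemble_features <- function(pop, grid) {
  if (!inherits(pop, "grip_population"))
    stop_param("pop", "must be a grip_population")
  if (!inherits(grid, "window_grid"))
    stop_param("grid", "must be a window_grid")
  trials <- pop$trials
  n_w <- nrow(grid)
  n_p <- 6L * pop$n_repetitions
  n_n <- pop$n_neurons

  expected <- n_p * n_n
  if (nrow(trials) != expected || anyDuplicated(trials[c("neuron_id", "pseudo_trial")]))
    stop(sprintf("incomplete pairing: expected one trial per (neuron, pseudo-trial); got %d rows",
                 nrow(trials)), call. = FALSE)

  spk <- split(pop$spikes$spike_time_ms, factor(pop$spikes$trial_id,
                                                levels = trials$trial_id))
  raw <- array(0, dim = c(n_p, n_w, n_n))
  for (j in seq_len(nrow(trials))) {
    raw[trials$pseudo_trial[j], , trials$neuron_id[j]] <-
      windowed_rates(spk[[j]], grid)
  }

  maxima <- apply(raw, 3L, max)
  dropped <- which(maxima <= 0)
  if (length(dropped) > 0L)
    warning(sprintf("dropping %d silent neuron(s) with no spikes in any window: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  kept <- setdiff(seq_len(n_n), dropped)
  if (length(kept) == 0L)
    stop("all neurons are silent; nothing to assemble", call. = FALSE)
  values <- raw[, , kept, drop = FALSE]
  for (idx in seq_along(kept))
    values[, , idx] <- values[, , idx] / maxima[kept[idx]]

  info <- unique(trials[order(trials$pseudo_trial),
                        c("pseudo_trial", "object_id", "grip_label")])
  rownames(info) <- NULL

  structure(
    list(values = values, grid = grid, trial_info = info,
         taxonomy = pop$taxonomy, timeline = pop$timeline,
         neuron_ids = kept, norm_constants = maxima[kept],
         dropped_neurons = dropped),
    class = "grip_features")
}

#' @export
print.grip_features <- function(x, ...) {
  cat(sprintf("<grip_features> %d pseudo-trials x %d windows (bin %g ms, step %g ms) x %d neurons\n",
              dim(x$values)[1], dim(x$values)[2], attr(x$grid, "bin_width"),
              attr(x$grid, "step"), dim(x$values)[3]))
  invisible(x)
}

# flatten the feature array to an (n_pseudo*n_windows) x n_neurons matrix,
# rows ordered window-within-trial; returns matrix plus row index
flatten_features <- function(features) {
  d <- dim(features$values)
  x <- matrix(aperm(features$values, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  idx <- data.frame(pseudo_trial = rep(features$trial_info$pseudo_trial,
                                       each = d[2]),
                    window = rep.int(seq_len(d[2]), d[1]))
  list(x = x, idx = idx)
}
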