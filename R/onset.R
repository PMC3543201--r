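#' Population nFR time course for one object
#'
#' Averages the normalized firing rate over neurons and over the
#' pseudo-trials of one object, per analysis window — the population PSTH
#' used for onset detection and for population-response figures.  The SD
#' reported alongside is taken over the per-trial population means (the
#' trial-to-trial variability of the population response).
#'
#' @param features A [assemble_features()] object.
#' @param object_id Object index 1..6.
#' @return Data frame with `window_end`, `mean`, `sd` (one row per window).
#' @export
population_nfr <- function(features, object_id) {
  info <- features$trial_info
  if (!object_id %in% info$object_id)
    stop(sprintf("unknown object_id %s; dataset has objects %s",
                 format(object_id),
                 paste(sort(unique(info$object_id)), collapse = ", ")),
         call. = FALSE)
  rows <- which(info$object_id == object_id)
  v <- features$values[rows, , , drop = FALSE]
  per_trial <- apply(v, c(1L, 2L), mean)              # trials x windows
  data.frame(window_end = features$grid$end,
             mean = colMeans(per_trial),
             sd = apply(per_trial, 2L, stats::sd))
}

#' Detect the population response onset by baseline thresholding
#'
#' The onset threshold is `baseline_mean + multiplier * baseline_sd`, with
#' baseline statistics computed over the analysis windows lying fully inside
#' the baseline window (the first 400 ms of object presentation,
#' [-1800, -1400] ms, by default).  The onset `t_onset` is the end time of
#' the first window that begins a run of at least `persistence` consecutive
#' windows strictly above threshold; the persistence requirement suppresses
#' single-window Poisson flukes.  If the baseline is degenerate (sd = 0) the
#' threshold equals the baseline mean and the strict inequality still
#' applies.
#'
#' @param series Numeric vector: population nFR per window (e.g. the `mean`
#'   column of [population_nfr()]).
#' @param grid The [make_window_grid()] grid the series was computed on.
#' @param baseline_window Length-2 interval (ms) for baseline statistics.
#' @param persistence Number of consecutive supra-threshold windows
#'   required.  The default (`NULL`) uses `ceiling(bin_width/step) + 1`
#'   windows, i.e. the run must outlast one full window length: with a 10 ms
#'   step consecutive windows share most of their spikes, so a run shorter
#'   than the window width can be produced by a single Poisson burst.
#' @param multiplier Threshold multiplier on the baseline SD (default 2.5).
#' @return List of class `onset_result`: `t_onset` (ms, `NA` if not
#'   detected), `threshold`, `baseline_mean`, `baseline_sd`, `detected`.
#' @export
detect_onset <- function(series, grid, baseline_window = c(-1800, -1400),
                         persistence = NULL, multiplier = 2.5) {
  if (length(series) != nrow(grid))
    stop_param("series", "length must match the number of grid windows")
  persistence <- persistence %||% default_persistence(grid)
  check_scalar_number(persistence, "persistence", positive = TRUE,
                      integerish = TRUE)
  check_scalar_number(multiplier, "multiplier")
  base_idx <- which(grid$start >= baseline_window[1] &
                    grid$end <= baseline_window[2])
  if (length(base_idx) < 2L)
    stop_param("baseline_window", "must cover at least 2 analysis windows")
  bm <- mean(series[base_idx])
  bs <- stats::sd(series[base_idx])
  thr <- bm + multiplier * bs
  above <- series > thr
  r <- rle(above)
  run_start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) {
    return(structure(list(t_onset = NA_real_, threshold = thr,
                          baseline_mean = bm, baseline_sd = bs,
                          detected = FALSE),
                     class = "onset_result"))
  }
  w <- run_start[hit[1L]]
  structure(list(t_onset = grid$end[w], threshold = thr,
                 baseline_mean = bm, baseline_sd = bs, detected = TRUE),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<onset_result> t_onset = %g ms (threshold %.4g)\n",
                x$t_onset, x$threshold))
  else
    cat(sprintf("<onset_result> not detected (threshold %.4g)\n", x$threshold))
  invisible(x)
}

#' Per-object population onsets
#'
#' Runs [detect_onset()] on the [population_nfr()] series of every object of
#' the dataset.
#'
#' @inheritParams detect_onset
#' @param features A [assemble_features()] object.
#' @return Data frame: `object_id`, `t_onset_ms`, `threshold`,
#'   `baseline_mean`, `baseline_sd`, `detected`.
#' @export
object_onsets <- function(features, baseline_window = NULL, persistence = NULL,
                          multiplier = 2.5) {
  baseline_window <- baseline_window %||% features$timeline$baseline_window
  objs <- sort(unique(features$trial_info$object_id))
  out <- lapply(objs, function(o) {
    res <- detect_onset(population_nfr(features, o)$mean, features$grid,
                        baseline_window, persistence, multiplier)
    data.frame(object_id = o, t_onset_ms = res$t_onset,
               threshold = res$threshold, baseline_mean = res$baseline_mean,
               baseline_sd = res$baseline_sd, detected = res$detected)
  })
  do.call(rbind, out)
}

# default persistence: the supra-threshold run must span one full window
# width (plus one step) so that overlapping windows fed by a single burst
# cannot trigger a detection
default_persistence <- function(grid) {
  max(2L, as.integer(ceiling(attr(grid, "bin_width") / attr(grid, "step"))) + 1L)
}
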