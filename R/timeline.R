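#' Trial timeline of the reach-to-grasp task
#'
#' All times are in milliseconds relative to the key-release event (t = 0,
#' start of the movement phase).  The analysis epoch runs from 1800 ms before
#' to 200 ms after key release; the first 400 ms of the object presentation
#' phase ([-1800, -1400] ms) serve as the baseline window for onset
#' detection.  Movement duration (key release to grasp completion) is drawn
#' per trial from a normal distribution truncated below at 50 ms.
#'
#' @param epoch Numeric length-2, analysis epoch in ms (default
#'   `c(-1800, 200)`).
#' @param baseline_window Numeric length-2, baseline interval in ms
#'   (default `c(-1800, -1400)`).
#' @param movement_duration_mean,movement_duration_sd Mean and SD of the
#'   movement duration in ms.  Defaults (334, 113) match the original object
#'   set; the special set used (407, 192).
#' @return An object of class `task_timeline`.
#' @examples
#' task_timeline()
#' task_timeline(movement_duration_mean = 407, movement_duration_sd = 192)
#' @export
task_timeline <- function(epoch = c(-1800, 200),
                          baseline_window = c(-1800, -1400),
                          movement_duration_mean = 334,
                          movement_duration_sd = 113) {
  if (length(epoch) != 2L || epoch[1] >= epoch[2])
    stop_param("epoch", "must be an increasing (start, end) pair")
  if (length(baseline_window) != 2L || baseline_window[1] >= baseline_window[2])
    stop_param("baseline_window", "must be an increasing (start, end) pair")
  if (baseline_window[1] < epoch[1] || baseline_window[2] > 0)
    stop_param("baseline_window", "must lie within the pre-movement epoch")
  check_scalar_number(movement_duration_mean, "movement_duration_mean",
                      positive = TRUE)
  check_scalar_number(movement_duration_sd, "movement_duration_sd")
  if (movement_duration_sd < 0)
    stop_param("movement_duration_sd", "must be >= 0")
  structure(
    list(epoch = as.numeric(epoch),
         baseline_window = as.numeric(baseline_window),
         key_release = 0,
         movement_duration_mean = movement_duration_mean,
         movement_duration_sd = movement_duration_sd),
    class = "task_timeline")
}

#' @export
print.task_timeline <- function(x, ...) {
  cat(sprintf("<task_timeline> epoch [%g, %g] ms, baseline [%g, %g] ms, t_mov %g +/- %g ms\n",
              x$epoch[1], x$epoch[2], x$baseline_window[1], x$baseline_window[2],
              x$movement_duration_mean, x$movement_duration_sd))
  invisible(x)
}
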