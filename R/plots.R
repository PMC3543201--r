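#' Population PSTH panel
#'
#' Plots the mean population nFR time course of every object, with the
#' detected onset (dashed) and the mean movement end (dotted) marked, plus
#' the key-release event at t = 0.
#'
#' @param features A [assemble_features()] object.
#' @param pop The originating [generate_population()] dataset (for movement
#'   ends); optional.
#' @param persistence,multiplier Onset-detection settings.
#' @return A ggplot object.
#' @export
plot_population_nfr <- function(features, pop = NULL, persistence = NULL,
                                multiplier = 2.5) {
  objs <- sort(unique(features$trial_info$object_id))
  df <- do.call(rbind, lapply(objs, function(o) {
    s <- population_nfr(features, o)
    s$object <- sprintf("%d: %s", o, features$taxonomy$objects[o])
    s$object_id <- o
    s
  }))
  ons <- object_onsets(features, persistence = persistence,
                       multiplier = multiplier)
  ons$object <- sprintf("%d: %s", ons$object_id,
                        features$taxonomy$objects[ons$object_id])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_end, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "black") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(data = ons[ons$detected, ],
                        ggplot2::aes(xintercept = .data$t_onset_ms),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~object) +
    ggplot2::labs(x = "time from key release (ms)", y = "population nFR",
                  title = sprintf("Population response, %s set",
                                  features$taxonomy$set_name)) +
    ggplot2::theme_minimal()
  if (!is.null(pop)) {
    tm <- stats::aggregate(movement_end_ms ~ object_id, pop$trials, mean)
    tm$object <- sprintf("%d: %s", tm$object_id,
                         features$taxonomy$objects[tm$object_id])
    p <- p + ggplot2::geom_vline(data = tm,
                                 ggplot2::aes(xintercept = .data$movement_end_ms),
                                 colour = "darkgreen", linetype = "dotted")
  }
  p
}

#' Recognition ratio versus window width
#'
#' @param sweep A [sweep_bin_widths()] result.
#' @return A ggplot object: mean RR +/- SD per bin width, one line per
#'   (scheme, k) condition.
#' @export
plot_rr_sweep <- function(sweep) {
  df <- as.data.frame(sweep)
  df$condition <- sprintf("%s, %d grips", df$scheme, df$k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_width, y = .data$rr_mean,
                                   colour = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rr_mean - .data$rr_sd,
                                        ymax = .data$rr_mean + .data$rr_sd),
                           width = 4) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window width (ms)", y = "recognition ratio (%)",
                  colour = NULL,
                  title = sprintf("Classifier performance, %s set",
                                  df$set[1])) +
    ggplot2::theme_minimal()
}

#' Actual-versus-predicted raster of one decoding repeat
#'
#' Trials are sorted by actual grip on the x axis (one column per test
#' window); the y axis shows the class predicted for each window.  Correct
#' classifications superimpose on the actual-class band; isolated marks off
#' the band are errors plotted at the predicted class.
#'
#' @param report A [run_decoding()] report (its first repeat is shown).
#' @return A ggplot object.
#' @export
plot_prediction_raster <- function(report) {
  fr <- report$first_repeat
  classes <- c("baseline", sort(setdiff(unique(as.character(fr$truth)),
                                        "baseline")))
  ord <- order(fr$trial_info$object_id, fr$trial_info$pseudo_trial)
  pred <- fr$predictions[ord, , drop = FALSE]
  truth <- fr$truth[ord, , drop = FALSE]
  n_w <- ncol(pred)
  df <- data.frame(
    x = rep(seq_len(nrow(pred) * n_w) / n_w, 2),
    class = factor(c(as.character(t(truth)), as.character(t(pred))),
                   levels = classes),
    what = rep(c("actual", "predicted"), each = length(pred)))
  correct <- as.character(t(truth)) == as.character(t(pred))
  df$correct <- c(correct, correct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$class)) +
    ggplot2::geom_point(data = df[df$what == "actual", ],
                        shape = 21, size = 1.6, colour = "black", stroke = 0.4) +
    ggplot2::geom_point(data = df[df$what == "predicted", ],
                        shape = 4, size = 1, colour = "red", alpha = 0.6) +
    ggplot2::labs(x = "test trial (sorted by actual grip)",
                  y = "class",
                  title = sprintf("%s discrimination, %d classes, %g ms windows",
                                  report$scheme, report$n_classes,
                                  report$bin_width)) +
    ggplot2::theme_minimal()
}

#' Write the standard figure set of a pipeline run
#'
#' Renders the population-PSTH panel, the RR-versus-bin-width curves and the
#' prediction raster to vector-graphics (PDF) files in `dir`.  Panels whose
#' inputs are missing are skipped with a message.
#'
#' @param dir Output directory (created if needed).
#' @param features,pop Inputs for the PSTH panel.
#' @param sweep A [sweep_bin_widths()] result (RR curves).
#' @param report A [run_decoding()] report (raster).
#' @return Invisibly, the paths written.
#' @export
render_outputs <- function(dir, features = NULL, pop = NULL, sweep = NULL,
                           report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save_one <- function(name, plot) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = 8, height = 5)
    path
  }
  if (!is.null(features)) {
    paths <- c(paths, save_one("population_nfr.pdf",
                               plot_population_nfr(features, pop)))
  } else message("no features given; skipping the population-PSTH panel")
  if (!is.null(sweep) && nrow(sweep) > 0L) {
    paths <- c(paths, save_one("rr_vs_binwidth.pdf", plot_rr_sweep(sweep)))
  } else message("no sweep results; skipping the RR-vs-binwidth panel")
  if (!is.null(report)) {
    paths <- c(paths, save_one("prediction_raster.pdf",
                               plot_prediction_raster(report)))
  } else message("no decoding report; skipping the prediction raster")
  invisible(paths)
}
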