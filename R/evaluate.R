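#' Sweep window widths through the full decoding chain
#'
#' Re-runs features -> onset/labeling -> decoding for every bin width and
#' every requested scheme and grip count, with the *same* trial splits in
#' every condition (splits are defined on pseudo-trial ids, which do not
#' depend on the grid), so conditions are paired for the nonparametric
#' comparisons.
#'
#' @param pop A [generate_population()] dataset.
#' @param bin_widths Numeric vector of window widths in ms (default
#'   `seq(25, 200, 25)`).
#' @param schemes Subset of `c("direct", "hierarchical")`.
#' @param ks Subset of `c(4, 6)`.
#' @param step,persistence,multiplier,nu,scope Pipeline settings.
#' @param train_fraction,n_repeats,seed Split settings, see [split_trials()].
#' @return A `sweep_result`: data frame with one row per (bin_width, scheme,
#'   k): `bin_width`, `scheme`, `k`, `set`, `rr_mean`, `rr_sd`, plus
#'   attributes `rr` (per-repeat RR matrix, repeats x conditions) and
#'   `reports` (the full `decoding_report`s).
#' @export
sweep_bin_widths <- function(pop, bin_widths = seq(25, 200, by = 25),
                             schemes = "direct", ks = 6,
                             step = 10, persistence = NULL, multiplier = 2.5,
                             nu = 0.1, scope = "grip",
                             train_fraction = 0.25, n_repeats = 50, seed = 1L) {
  if (length(bin_widths) < 1L)
    stop_param("bin_widths", "must name at least one window width")
  if (!all(schemes %in% c("direct", "hierarchical")))
    stop_param("schemes", "must be a subset of direct, hierarchical")
  if (!all(ks %in% c(4, 6))) stop_param("ks", "must be a subset of 4, 6")

  splits <- NULL
  rows <- list()
  reports <- list()
  for (bw in bin_widths) {
    grid <- make_window_grid(bw, step, pop$timeline$epoch)
    feats <- tryCatch(assemble_features(pop, grid),
                      error = function(e) stop(sprintf("bin width %g ms: %s",
                                                      bw, conditionMessage(e)),
                                               call. = FALSE))
    if (is.null(splits))
      splits <- split_trials(feats$trial_info, train_fraction, n_repeats, seed)
    for (k in ks) {
      labels <- label_windows(feats, persistence, multiplier, k)
      for (sc in schemes) {
        rep <- run_decoding(feats, labels, splits, sc, nu = nu, scope = scope,
                            seed = seed)
        key <- sprintf("bw%g_%s_k%d", bw, sc, k)
        reports[[key]] <- rep
        rows[[key]] <- data.frame(bin_width = bw, scheme = sc, k = k,
                                  set = pop$taxonomy$set_name,
                                  rr_mean = rep$rr_mean, rr_sd = rep$rr_sd)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rr") <- vapply(reports, function(r) r$rr,
                            numeric(length(reports[[1]]$rr)))
  attr(out, "reports") <- reports
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Friedman test on paired recognition ratios
#'
#' Compares two or more conditions (e.g. direct vs hierarchical scheme, or
#' original vs special object set) across paired blocks — typically the
#' window widths, the factor shared by all conditions.  Thin wrapper around
#' [stats::friedman.test()] (within-block average ranks, tie-corrected
#' chi-square statistic, `conditions - 1` degrees of freedom); the decision
#' threshold used throughout the package is p <= 0.01.
#'
#' @param rr Numeric matrix, blocks x conditions (complete, unreplicated).
#' @return The `htest` from [stats::friedman.test()].
#' @export
friedman_rr <- function(rr) {
  rr <- as.matrix(rr)
  if (any(!is.finite(rr)))
    stop("friedman_rr needs a complete block design: non-finite entries found",
         call. = FALSE)
  if (ncol(rr) < 2L || nrow(rr) < 2L)
    stop_param("rr", "needs >= 2 conditions (columns) and >= 2 blocks (rows)")
  out <- stats::friedman.test(rr)
  if (is.nan(out$statistic)) {
    # every block fully tied: no evidence against exchangeability
    out$statistic[] <- 0
    out$p.value <- 1
  }
  out
}

#' Kruskal-Wallis test of bin-width influence
#'
#' Tests whether the distribution of per-repeat recognition ratios differs
#' across groups (the window widths).  Thin wrapper around
#' [stats::kruskal.test()] (rank-sum H statistic with tie correction,
#' chi-square p-value); decision threshold p <= 0.01.
#'
#' @param rr Numeric vector of recognition ratios.
#' @param groups Group labels (e.g. the bin width of each value).
#' @return The `htest` from [stats::kruskal.test()].
#' @export
kruskal_rr <- function(rr, groups) {
  if (length(rr) != length(groups))
    stop_param("groups", "must align with 'rr'")
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop_param("groups", "needs >= 2 groups")
  if (any(table(groups) < 2L))
    stop_param("groups", "every group needs >= 2 samples")
  out <- stats::kruskal.test(rr, groups)
  if (is.nan(out$statistic)) {
    # all observations identical: no evidence of a group effect
    out$statistic[] <- 0
    out$p.value <- 1
  }
  out
}
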