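#' Pipeline configuration
#'
#' Collects every tunable constant of the decoding chain in one list.
#' Defaults follow the task protocol where it fixes a value: epoch
#' [-1800, 200] ms, 10 ms step, baseline window [-1800, -1400] ms, threshold
#' multiplier 2.5, 25% training fraction; the remaining values (persistence,
#' nu, kernel width, repeat count) are documented package defaults.
#'
#' @param scenario Name of a packaged scenario ([reference_scenarios()]),
#'   or `NULL` when `input_dir` points at a dataset on disk.
#' @param input_dir Directory readable by [read_population()]; ignored when
#'   `scenario` is given.
#' @param bin_widths Window widths (ms) for the sweep.
#' @param step Window step (ms).
#' @param persistence,multiplier Onset detection, see [detect_onset()].
#' @param nu,gamma nu-SVM settings (`gamma = NULL` means `1/n_neurons`).
#' @param train_fraction,n_repeats,seed Split settings.
#' @param schemes,ks Conditions to sweep.
#' @param scope RR scope, see [recognition_ratio()].
#' @param raster_bin_width Bin width (ms) whose first-repeat predictions
#'   feed the raster figure.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = "paperlike", input_dir = NULL,
                            bin_widths = seq(25, 200, by = 25), step = 10,
                            persistence = NULL, multiplier = 2.5,
                            nu = 0.1, gamma = NULL,
                            train_fraction = 0.25, n_repeats = 50, seed = 1L,
                            schemes = c("direct", "hierarchical"), ks = c(4, 6),
                            scope = "grip", raster_bin_width = 100) {
  if (is.null(scenario) && is.null(input_dir))
    stop_param("scenario", "either a scenario name or an input_dir is required")
  cfg <- list(scenario = scenario, input_dir = input_dir,
              bin_widths = bin_widths, step = step, persistence = persistence,
              multiplier = multiplier, nu = nu, gamma = gamma,
              train_fraction = train_fraction, n_repeats = n_repeats,
              seed = as.integer(seed), schemes = schemes, ks = ks,
              scope = scope, raster_bin_width = raster_bin_width)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full decoding pipeline
#'
#' Simulates (or ingests) a population, sweeps the configured bin widths
#' through features -> onset -> labeling -> decoding for every (scheme, k)
#' condition, runs the nonparametric comparisons, and writes all artifacts
#' under one output directory: the echoed configuration (`config.yaml`),
#' onsets (`onsets.csv`), the sweep table (`sweep.csv`), a machine-readable
#' report (`report.json`: per-condition RR summaries, statistics) and the
#' standard figures.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed.  `NULL` skips all
#'   file output and returns the results only.
#' @return Invisibly, a list with `pop`, `onsets`, `sweep`, `stats`,
#'   `raster_report` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  pop <- stage("data", {
    if (!is.null(config$scenario)) generate_scenario(config$scenario)
    else read_population(config$input_dir)
  })
  sweep <- stage("sweep", sweep_bin_widths(
    pop, config$bin_widths, config$schemes, config$ks, config$step,
    config$persistence, config$multiplier, config$nu, config$scope,
    config$train_fraction, config$n_repeats, config$seed))

  feats <- stage("features", assemble_features(
    pop, make_window_grid(config$raster_bin_width, config$step,
                          pop$timeline$epoch)))
  onsets <- stage("onset", object_onsets(feats, persistence = config$persistence,
                                         multiplier = config$multiplier))

  stats_out <- list()
  rr <- attr(sweep, "rr")
  if (length(config$schemes) == 2L && length(config$bin_widths) >= 2L) {
    k0 <- max(config$ks)
    mat <- cbind(direct = sweep$rr_mean[sweep$scheme == "direct" & sweep$k == k0],
                 hierarchical = sweep$rr_mean[sweep$scheme == "hierarchical" &
                                              sweep$k == k0])
    stats_out$scheme_friedman <- friedman_rr(mat)
  }
  if (length(config$bin_widths) >= 2L) {
    k0 <- max(config$ks)
    sc0 <- config$schemes[1]
    keys <- sprintf("bw%g_%s_k%d", config$bin_widths, sc0, k0)
    stats_out$binwidth_kruskal <- kruskal_rr(
      c(rr[, keys]), rep(config$bin_widths, each = nrow(rr)))
  }

  raster_key <- sprintf("bw%g_%s_k%d", config$raster_bin_width,
                        config$schemes[1], max(config$ks))
  raster_report <- attr(sweep, "reports")[[raster_key]]

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_echo <- unclass(config)
    yaml::write_yaml(cfg_echo[!vapply(cfg_echo, is.null, logical(1))],
                     file.path(out_dir, "config.yaml"))
    utils::write.csv(onsets, file.path(out_dir, "onsets.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sweep), file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    report <- list(
      set = pop$taxonomy$set_name,
      n_neurons = pop$n_neurons, n_repetitions = pop$n_repetitions,
      seed = config$seed,
      conditions = lapply(attr(sweep, "reports"), function(r) {
        list(scheme = r$scheme, k = r$k, n_classes = r$n_classes,
             bin_width = r$bin_width, rr_mean = r$rr_mean, rr_sd = r$rr_sd,
             per_repeat_rr = r$rr, confusion = unclass(r$confusion))
      }),
      statistics = lapply(stats_out, function(h)
        list(statistic = unname(h$statistic), p_value = h$p.value)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fig_paths <- render_outputs(file.path(out_dir, "figures"),
                                features = feats, pop = pop, sweep = sweep,
                                report = raster_report)
    paths <- c(file.path(out_dir, c("config.yaml", "onsets.csv", "sweep.csv",
                                    "report.json")), fig_paths)
  }
  invisible(list(pop = pop, onsets = onsets, sweep = sweep,
                 stats = stats_out, raster_report = raster_report,
                 paths = paths))
}
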