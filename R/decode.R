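#' Label analysis windows as baseline or grip
#'
#' Every (pseudo-trial, window) pair receives exactly one label.  Windows
#' recorded during grip execution (ending after key release) carry the
#' trial's grip label.  Before key release, sub-threshold activity is
#' baseline: a window is labeled with the trial's grip only if it ends after
#' the trial's onset boundary *and* its population nFR (mean over the paired
#' neurons) is above the trial's onset threshold; preparatory windows that
#' have not (yet) crossed the threshold stay baseline.  The onset boundary of
#' a trial is resolved in order of preference: (i) the trial's own
#' population-nFR threshold crossing, thresholded against that trial's
#' baseline statistics; (ii) the per-object population onset; (iii) the
#' key-release event (t = 0) when no crossing is detected anywhere — so that
#' movement-phase windows still carry the grip label in unmodulated
#' datasets.
#'
#' @param features A [assemble_features()] object.
#' @param persistence,multiplier Onset-detection settings, see
#'   [detect_onset()].
#' @param k Number of grip classes (6 for object-level grips, 4 to apply the
#'   taxonomy's merge).
#' @return A `grip_labels` object: list with `labels` (character matrix,
#'   pseudo-trials x windows), `boundaries` (data frame `pseudo_trial`,
#'   `boundary_ms`, `source` in trial/object/key_release), `k`, `grid` and
#'   `trial_info`.
#' @export
label_windows <- function(features, persistence = NULL, multiplier = 2.5, k = 6) {
  if (!k %in% c(4, 6)) stop_param("k", "must be 4 or 6")
  info <- features$trial_info
  grid <- features$grid
  bw <- features$timeline$baseline_window
  obj <- object_onsets(features, bw, persistence, multiplier)

  key_release <- features$timeline$key_release
  n_p <- nrow(info)
  boundary <- numeric(n_p)
  source <- character(n_p)
  grip <- info$grip_label
  if (k == 4) grip <- merge_to_four(features$taxonomy, grip)
  labels <- matrix("baseline", n_p, nrow(grid))
  for (p in seq_len(n_p)) {
    series <- apply(features$values[p, , , drop = FALSE], 2L, mean)
    res <- detect_onset(series, grid, bw, persistence, multiplier)
    if (res$detected) {
      boundary[p] <- res$t_onset
      source[p] <- "trial"
    } else {
      o <- obj[obj$object_id == info$object_id[p], ]
      if (isTRUE(o$detected)) {
        boundary[p] <- o$t_onset_ms
        source[p] <- "object"
      } else {
        boundary[p] <- key_release
        source[p] <- "key_release"
      }
    }
    is_grip <- grid$end > key_release |
      (grid$end > boundary[p] & series > res$threshold)
    labels[p, is_grip] <- grip[p]
  }

  structure(
    list(labels = labels,
         boundaries = data.frame(pseudo_trial = info$pseudo_trial,
                                 boundary_ms = boundary, source = source),
         k = k, grid = grid, trial_info = info, taxonomy = features$taxonomy),
    class = "grip_labels")
}

#' Seeded stratified trial splits for train/test cross-validation
#'
#' Splits pseudo-trials (never individual windows) into training and test
#' partitions, stratified by object so every grip class appears in both
#' partitions of every repeat.  With the task's 8 repetitions per object and
#' the default 25% training fraction, each repeat trains on 2 and tests on 6
#' trials per object.
#'
#' @param trial_info Data frame with `pseudo_trial` and `object_id` (e.g.
#'   `features$trial_info`).
#' @param train_fraction Fraction of trials per object used for training
#'   (default 0.25); must leave at least one training and one test trial per
#'   object.
#' @param n_repeats Number of random splits.
#' @param seed Integer seed.
#' @return A `split_spec`: list with `repeats` (list of
#'   `list(train =, test =)` pseudo-trial ids), `train_fraction`, `seed`.
#' @export
split_trials <- function(trial_info, train_fraction = 0.25, n_repeats = 50,
                         seed = 1L) {
  check_scalar_number(train_fraction, "train_fraction", positive = TRUE)
  check_scalar_number(n_repeats, "n_repeats", positive = TRUE, integerish = TRUE)
  if (train_fraction >= 1)
    stop_param("train_fraction", "must be < 1 (the test partition may not be empty)")
  per_obj <- split(trial_info$pseudo_trial, trial_info$object_id)
  sizes <- lengths(per_obj)
  if (any(sizes < 2L))
    stop(sprintf("stratification impossible: object(s) %s have fewer than 2 trials",
                 paste(names(per_obj)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  n_train <- pmax(1L, round(train_fraction * sizes))
  if (any(n_train >= sizes))
    stop_param("train_fraction", "leaves an object with no test trials")
  reps <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      train <- unlist(mapply(function(ids, nt) sample(ids, nt),
                             per_obj, n_train, SIMPLIFY = FALSE),
                      use.names = FALSE)
      list(train = sort(train),
           test = sort(setdiff(trial_info$pseudo_trial, train)))
    })
  })
  structure(list(repeats = reps, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Build the training design for a set of pseudo-trials: nFR rows plus labels,
# with seeded subsampling so no class dominates nu-SVM training.  Every class
# is capped at the median count of the grip classes (the baseline class and,
# in 4-grip mode, the merged class are the ones affected).
training_design <- function(flat, labels, train_ids, balance = TRUE) {
  rows <- which(flat$idx$pseudo_trial %in% train_ids)
  y <- labels$labels[cbind(match(flat$idx$pseudo_trial[rows],
                                 labels$trial_info$pseudo_trial),
                           flat$idx$window[rows])]
  if (balance) {
    counts <- table(y)
    grip_counts <- counts[setdiff(names(counts), "baseline")]
    if (length(grip_counts) > 0L) {
      cap <- ceiling(stats::median(grip_counts))
      keep <- unlist(lapply(names(counts), function(cl) {
        i <- which(y == cl)
        if (length(i) > cap) sample(i, cap) else i
      }), use.names = FALSE)
      rows <- rows[sort(keep)]
      y <- y[sort(keep)]
    }
  }
  list(x = flat$x[rows, , drop = FALSE], y = factor(y))
}

# nu-SVC is only feasible when nu <= 2*min(n_i, n_j)/(n_i + n_j) for every
# class pair; cap nu just below the bound implied by the realized counts.
# Heavily quantized nFR designs (many duplicate rows, e.g. all-zero baseline
# windows) can still push a one-vs-one subproblem into a degenerate solution;
# in that case retry deterministically with a halved nu.
fit_nusvm <- function(x, y, nu, gamma) {
  n <- table(y)
  bound <- 2 * min(n) / (min(n) + max(n))
  nu_eff <- min(nu, 0.99 * bound)
  for (i in 0:1) {
    m <- tryCatch(
      e1071::svm(x, y, type = "nu-classification", kernel = "radial",
                 nu = nu_eff / 2^i, gamma = gamma, scale = FALSE),
      error = function(e) e)
    if (!inherits(m, "error")) return(m)
  }
  # identical feature vectors occurring in several classes (e.g. empty
  # windows labeled both baseline and grip) make every nu infeasible for
  # that one-vs-one pair; the C-parameterization of the same machine
  # tolerates such inseparable duplicates
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = 1, gamma = gamma, scale = FALSE)
}

#' Train the direct multi-class grip classifier
#'
#' Fits a single nu-SVM with radial-basis kernel over k + 1 classes
#' (baseline plus the k grip types) on the nFR feature vectors of the
#' training trials' windows.  Training windows are subsampled (seeded by the
#' caller's RNG state) so that no class exceeds the median grip-class count.
#'
#' @param features A [assemble_features()] object.
#' @param labels A [label_windows()] labeling with matching grid.
#' @param train_ids Pseudo-trial ids of the training partition.
#' @param nu nu-SVM parameter (default 0.1): an upper bound on the fraction
#'   of margin errors.  Small values fit the near-separable nFR clusters
#'   tightly; large values (e.g. 0.5) force at least half of the training
#'   windows inside the margin and cost several RR points.
#' @param gamma RBF kernel width (default `1 / n_neurons`).
#' @return A `grip_classifier` of scheme `"direct"`.
#' @export
train_direct <- function(features, labels, train_ids, nu = 0.1, gamma = NULL) {
  flat <- flatten_features(features)
  gamma <- gamma %||% (1 / ncol(flat$x))
  d <- training_design(flat, labels, train_ids)
  classes <- c("baseline", grip_classes(features$taxonomy, labels$k))
  missing <- setdiff(classes, levels(d$y))
  if (length(missing) > 0L)
    stop(sprintf("training windows contain no examples of class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(scheme = "direct", model = fit_nusvm(d$x, d$y, nu, gamma),
                 k = labels$k, nu = nu, gamma = gamma,
                 bin_width = attr(features$grid, "bin_width")),
            class = "grip_classifier")
}

#' Train the hierarchical (two-stage) grip classifier
#'
#' Stage 1 is a binary nu-SVM separating baseline from above-threshold
#' (grip) windows; stage 2 is a k-class nu-SVM trained on grip windows only.
#' At prediction time stage 2 is invoked only where stage 1 reports activity.
#'
#' @inheritParams train_direct
#' @return A `grip_classifier` of scheme `"hierarchical"`.
#' @export
train_hierarchical <- function(features, labels, train_ids, nu = 0.1,
                               gamma = NULL) {
  flat <- flatten_features(features)
  gamma <- gamma %||% (1 / ncol(flat$x))
  d <- training_design(flat, labels, train_ids)
  is_base <- d$y == "baseline"
  if (all(is_base) || !any(is_base))
    stop("stage 1 needs both baseline and grip training windows", call. = FALSE)
  classes <- grip_classes(features$taxonomy, labels$k)
  missing <- setdiff(classes, unique(as.character(d$y[!is_base])))
  if (length(missing) > 0L)
    stop(sprintf("training windows contain no examples of class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  y1 <- factor(ifelse(is_base, "baseline", "active"))
  stage1 <- fit_nusvm(d$x, y1, nu, gamma)
  stage2 <- fit_nusvm(d$x[!is_base, , drop = FALSE], factor(d$y[!is_base]),
                      nu, gamma)
  structure(list(scheme = "hierarchical", stage1 = stage1, stage2 = stage2,
                 k = labels$k, nu = nu, gamma = gamma,
                 bin_width = attr(features$grid, "bin_width")),
            class = "grip_classifier")
}

#' Continuous per-window predictions
#'
#' Produces one predicted label per (test pseudo-trial, analysis window), in
#' time order — the continuous decoding stream a prosthesis controller would
#' consume.
#'
#' @param object A `grip_classifier`.
#' @param features A [assemble_features()] object on the same bin width the
#'   classifier was trained with.
#' @param test_ids Pseudo-trial ids to predict (default: all trials).
#' @param ... Unused.
#' @return Character matrix (test trials x windows) with `test_ids` as row
#'   names.
#' @export
predict_continuous <- function(object, features, test_ids = NULL, ...) {
  if (!inherits(object, "grip_classifier"))
    stop_param("object", "must be a grip_classifier")
  bw <- attr(features$grid, "bin_width")
  if (!isTRUE(all.equal(bw, object$bin_width)))
    stop(sprintf("bin-width mismatch: classifier trained at %g ms, features at %g ms",
                 object$bin_width, bw), call. = FALSE)
  test_ids <- test_ids %||% features$trial_info$pseudo_trial
  flat <- flatten_features(features)
  rows <- which(flat$idx$pseudo_trial %in% test_ids)
  x <- flat$x[rows, , drop = FALSE]
  if (object$scheme == "direct") {
    pred <- as.character(stats::predict(object$model, x))
  } else {
    s1 <- as.character(stats::predict(object$stage1, x))
    pred <- rep("baseline", nrow(x))
    act <- which(s1 == "active")
    if (length(act) > 0L)
      pred[act] <- as.character(stats::predict(object$stage2,
                                               x[act, , drop = FALSE]))
  }
  n_w <- nrow(features$grid)
  out <- matrix(pred, ncol = n_w, byrow = TRUE)
  rownames(out) <- as.character(flat$idx$pseudo_trial[rows[seq(1, length(rows), by = n_w)]])
  out
}

#' @export
predict.grip_classifier <- function(object, features, test_ids = NULL, ...) {
  predict_continuous(object, features, test_ids, ...)
}

#' Recognition ratio
#'
#' The percentage of windows whose predicted label matches the true label.
#' With `scope = "grip"` (the default) only windows whose *true* label is a
#' grip enter the denominator — the proportion of grips correctly identified
#' among those classified; a grip window predicted as baseline counts as an
#' error.  With `scope = "all"` baseline windows are included too.
#'
#' @param predictions,truth Label vectors or matrices of equal shape.
#' @param scope `"grip"` or `"all"`.
#' @return RR in percent (0-100).
#' @export
recognition_ratio <- function(predictions, truth, scope = c("grip", "all")) {
  scope <- match.arg(scope)
  p <- as.character(predictions)
  t <- as.character(truth)
  if (length(p) != length(t))
    stop_param("predictions", "must align with 'truth'")
  if (scope == "grip") {
    keep <- t != "baseline"
    if (!any(keep))
      stop("recognition ratio undefined: no grip-labeled windows in scope",
           call. = FALSE)
    p <- p[keep]; t <- t[keep]
  }
  100 * mean(p == t)
}

#' Run repeated train/test decoding
#'
#' Executes the full decoding protocol for one bin width: for each seeded
#' 25%/75% split, train the chosen scheme on the training trials' windows and
#' predict every window of the test trials; report the recognition ratio per
#' repeat, its mean and SD, the pooled confusion counts, and the per-window
#' predictions of the first repeat (raster material).
#'
#' @param features A [assemble_features()] object.
#' @param labels A [label_windows()] labeling (its `k` sets the class count).
#' @param splits A [split_trials()] specification.
#' @param scheme `"direct"` or `"hierarchical"`.
#' @param nu,gamma nu-SVM settings, see [train_direct()].
#' @param scope RR scope, see [recognition_ratio()].
#' @param seed Seed for the per-repeat training subsampling.
#' @return A `decoding_report`: list with `scheme`, `k`, `bin_width`,
#'   `rr` (per-repeat %), `rr_mean`, `rr_sd`, `confusion` (true x predicted,
#'   pooled over repeats), `first_repeat` (list with `predictions`, `truth`,
#'   `trial_info`).
#' @export
run_decoding <- function(features, labels, splits, scheme = c("direct", "hierarchical"),
                         nu = 0.1, gamma = NULL, scope = "grip", seed = 1L) {
  scheme <- match.arg(scheme)
  trainer <- if (scheme == "direct") train_direct else train_hierarchical
  classes <- c("baseline", grip_classes(features$taxonomy, labels$k))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  rr <- numeric(length(splits$repeats))
  first <- NULL
  for (r in seq_along(splits$repeats)) {
    sp <- splits$repeats[[r]]
    model <- with_seed(seed + r, trainer(features, labels, sp$train, nu, gamma))
    pred <- predict_continuous(model, features, sp$test)
    truth <- labels$labels[match(sort(sp$test), labels$trial_info$pseudo_trial), ,
                           drop = FALSE]
    rr[r] <- recognition_ratio(pred, truth, scope)
    conf <- conf + table(factor(truth, classes), factor(pred, classes))
    if (r == 1L)
      first <- list(predictions = pred, truth = truth,
                    trial_info = features$trial_info[
                      match(sort(sp$test), features$trial_info$pseudo_trial), ])
  }
  structure(
    list(scheme = scheme, k = labels$k,
         bin_width = attr(features$grid, "bin_width"),
         n_classes = length(classes), rr = rr,
         rr_mean = mean(rr), rr_sd = stats::sd(rr),
         confusion = conf, scope = scope, first_repeat = first),
    class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> %s scheme, %d classes (baseline + %d grips), bin %g ms\n",
              x$scheme, x$n_classes, x$k, x$bin_width))
  cat(sprintf("  RR (scope=%s): %.2f +/- %.2f %% over %d splits\n",
              x$scope, x$rr_mean, x$rr_sd, length(x$rr)))
  invisible(x)
}
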