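#' Write a population dataset as delimited text
#'
#' Writes three files under `dir`: `spikes.csv` (columns `neuron_id`,
#' `trial_id`, `object_id`, `grip_label`, `spike_time_ms`; one spike per
#' row), `events.csv` (columns `trial_id`, `object_id`, `movement_end_ms`,
#' plus `neuron_id`, `rep_index` and `pseudo_trial` carrying the
#' pseudo-population pairing), and `meta.yaml` (object set, timeline,
#' population size, generation seed).  Times are ms relative to key release.
#'
#' @param pop A [generate_population()] dataset.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- pop$trials
  sp <- merge(pop$spikes, tr[c("trial_id", "neuron_id", "object_id", "grip_label")],
              by = "trial_id", sort = FALSE)
  sp <- sp[order(match(sp$trial_id, tr$trial_id), sp$spike_time_ms),
           c("neuron_id", "trial_id", "object_id", "grip_label", "spike_time_ms")]
  spikes_path <- file.path(dir, "spikes.csv")
  events_path <- file.path(dir, "events.csv")
  meta_path <- file.path(dir, "meta.yaml")
  utils::write.csv(sp, spikes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(tr[c("trial_id", "object_id", "movement_end_ms",
                        "neuron_id", "rep_index", "pseudo_trial")],
                   events_path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(set = pop$taxonomy$set_name,
         timeline = list(epoch = pop$timeline$epoch,
                         baseline_window = pop$timeline$baseline_window,
                         movement_duration_mean = pop$timeline$movement_duration_mean,
                         movement_duration_sd = pop$timeline$movement_duration_sd),
         n_neurons = pop$n_neurons, n_repetitions = pop$n_repetitions,
         seed = pop$seed),
    meta_path)
  invisible(c(spikes_path, events_path, meta_path))
}

#' Read a population dataset from delimited text
#'
#' Reads the `spikes.csv` / `events.csv` / `meta.yaml` layout written by
#' [write_population()] and validates it: mandatory columns, spike times
#' within the epoch and sorted per trial, equal repetition counts per
#' (neuron, object), and a pairing that is a bijection per object.
#'
#' @param dir Directory holding the three files.
#' @return A `grip_population` (the `tuning` element is `NULL`: programmed
#'   rates are not part of the interchange format).
#' @export
read_population <- function(dir) {
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L)
      stop(sprintf("%s: missing column(s) %s", file,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  need(sp, c("neuron_id", "trial_id", "object_id", "grip_label",
             "spike_time_ms"), "spikes.csv")
  need(ev, c("trial_id", "object_id", "movement_end_ms", "neuron_id",
             "rep_index", "pseudo_trial"), "events.csv")
  timeline <- do.call(task_timeline, meta$timeline)
  taxonomy <- grip_taxonomy(meta$set)

  bad <- which(sp$spike_time_ms < timeline$epoch[1] |
               sp$spike_time_ms > timeline$epoch[2])
  if (length(bad) > 0L)
    stop(sprintf("spikes.csv: spike time(s) outside the epoch at row(s) %s",
                 paste(utils::head(bad, 5L) + 1L, collapse = ", ")),
         call. = FALSE)
  unsorted <- tapply(sp$spike_time_ms, sp$trial_id, is.unsorted)
  if (any(unsorted))
    stop(sprintf("spikes.csv: unsorted spike times in trial(s) %s",
                 paste(utils::head(names(which(unsorted)), 5L), collapse = ", ")),
         call. = FALSE)

  reps <- table(ev$neuron_id, ev$object_id)
  if (length(unique(c(reps))) != 1L)
    stop(sprintf("events.csv: unequal repetition counts per (neuron, object); found %s",
                 paste(sort(unique(c(reps))), collapse = ", ")), call. = FALSE)
  n_rep <- unique(c(reps))
  ok_pairing <- all(tapply(ev$pseudo_trial,
                           interaction(ev$neuron_id, ev$object_id),
                           function(p) length(unique(p)) == length(p)))
  if (!ok_pairing)
    stop("events.csv: pairing is not a bijection per (neuron, object)",
         call. = FALSE)

  trials <- ev[order(ev$neuron_id, ev$object_id, ev$rep_index),
               c("trial_id", "object_id", "movement_end_ms", "neuron_id",
                 "rep_index", "pseudo_trial")]
  trials <- data.frame(neuron_id = trials$neuron_id,
                       object_id = trials$object_id,
                       rep_index = trials$rep_index,
                       trial_id = trials$trial_id,
                       grip_label = taxonomy$grip_labels[trials$object_id],
                       pseudo_trial = trials$pseudo_trial,
                       movement_end_ms = trials$movement_end_ms)
  rownames(trials) <- NULL
  spikes <- data.frame(trial_id = sp$trial_id,
                       spike_time_ms = as.numeric(sp$spike_time_ms))
  structure(
    list(taxonomy = taxonomy, timeline = timeline, tuning = NULL,
         trials = trials, spikes = spikes,
         n_neurons = length(unique(ev$neuron_id)),
         n_repetitions = as.integer(n_rep),
         seed = meta$seed %||% NA_integer_),
    class = "grip_population")
}
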