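#' Grip taxonomy for a six-object turntable set
#'
#' The reach-to-grasp task presents six geometric objects mounted on a
#' rotating turntable; each object affords a characteristic grip.  Two object
#' sets exist.  In the *original* set the first three objects (cube, sphere,
#' cone) are all taken with a side grip; in the *special* set the first three
#' objects (sphere in groove, large cylinder in container, small sphere) share
#' thumb/finger-opposition features.  For four-grip analyses those three
#' objects are merged into a single class, leaving four grip classes.
#'
#' @param set `"original"` or `"special"`.
#' @return An object of class `grip_taxonomy`: a list with `set_name`,
#'   `objects` (6 object names), `grips` (grip type per object),
#'   `grip_labels` (`"g1"`..`"g6"`, the class labels used downstream),
#'   `merged_members` (indices of the objects collapsed for 4-grip analyses)
#'   and `merged_labels` (the 4-class label of each object).
#' @examples
#' tax <- grip_taxonomy("original")
#' tax$objects
#' merge_to_four(tax, c("baseline", "g1", "g2", "g5"))
#' @export
grip_taxonomy <- function(set = c("original", "special")) {
  set <- match.arg(set)
  if (set == "original") {
    objects <- c("cube", "sphere", "cone", "plate", "cylinder", "ring")
    grips <- c("side grip", "side grip", "side grip",
               "primitive precision grip", "finger prehension",
               "hook grip (index)")
  } else {
    objects <- c("sphere in groove", "large cylinder in container",
                 "small sphere", "large sphere", "small ring", "large ring")
    grips <- c("advanced precision grip",
               "finger prehension with thumb opposition", "side grip",
               "whole hand prehension", "hook grip (index)",
               "hook grip (4 fingers)")
  }
  merged_members <- 1:3
  grip_labels <- paste0("g", 1:6)
  merged_labels <- c(rep("g123", 3), paste0("g", 4:6))
  structure(
    list(set_name = set, objects = objects, grips = grips,
         grip_labels = grip_labels, merged_members = merged_members,
         merged_labels = merged_labels),
    class = "grip_taxonomy")
}

#' @export
print.grip_taxonomy <- function(x, ...) {
  cat(sprintf("<grip_taxonomy> %s set\n", x$set_name))
  df <- data.frame(object = x$objects, grip = x$grips,
                   label6 = x$grip_labels, label4 = x$merged_labels)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Collapse six grip labels to the four-grip taxonomy
#'
#' Maps the labels of the three merged objects onto a single class
#' (`"g123"`); the remaining grips and the `"baseline"` label pass through.
#' Idempotent: already-merged labels are returned unchanged.
#'
#' @param taxonomy A [grip_taxonomy()].
#' @param labels Character vector (or matrix) of labels among
#'   `"baseline"`, `"g1"`..`"g6"` or already-merged labels.
#' @return Labels with at most 4 grip classes, same shape as the input.
#' @export
merge_to_four <- function(taxonomy, labels) {
  if (!inherits(taxonomy, "grip_taxonomy"))
    stop_param("taxonomy", "must be a grip_taxonomy")
  map <- c(stats::setNames(taxonomy$merged_labels, taxonomy$grip_labels),
           stats::setNames(unique(taxonomy$merged_labels),
                           unique(taxonomy$merged_labels)),
           baseline = "baseline")
  out <- labels
  known <- labels %in% names(map)
  if (!all(known))
    stop_param("labels", sprintf("unknown label(s): %s",
               paste(unique(labels[!known]), collapse = ", ")))
  out[] <- map[labels]
  out
}

#' Grip class labels for a given number of grips
#'
#' @param taxonomy A [grip_taxonomy()].
#' @param k Number of grip classes, 4 or 6.
#' @return Character vector of the k grip class labels (baseline excluded).
#' @export
grip_classes <- function(taxonomy, k = 6) {
  if (!k %in% c(4, 6)) stop_param("k", "must be 4 or 6")
  if (k == 6) taxonomy$grip_labels else unique(taxonomy$merged_labels)
}
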