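#' The 13-class behavior ethogram
#'
#' The ethogram developed from the tag video footage: 13 behavior classes,
#' of which four (burst swimming, feeding, gliding, rolling) are excluded
#' from classifier training because too little labeled data could be
#' collected for them, leaving nine classes for classification.
#'
#' @return A data.frame with columns `name` and `included_in_classifier`.
#' @export
behavior_classes <- function() {
  excluded <- c("burst_swimming", "feeding", "gliding", "rolling")
  name <- c("backward_swimming", "boom", "gulping", "burst_swimming",
            "feeding", "forward_swimming", "gliding", "hovering", "turning",
            "listing", "resting", "rolling", "shaking")
  data.frame(name = name,
             included_in_classifier = !name %in% excluded,
             stringsAsFactors = FALSE)
}

#' Names of the nine classes retained for classification
#' @return Character vector of length 9.
#' @export
retained_classes <- function() {
  bc <- behavior_classes()
  bc$name[bc$included_in_classifier]
}

#' The default labeling hierarchy
#'
#' When an animal performs several behaviors at once (e.g., forward swimming
#' while booming), the earliest class in the hierarchy wins; booming
#' therefore outranks forward swimming. Only that ordering is normative;
#' the rest of this default is a configurable choice.
#'
#' @return Character vector: a permutation of the 13 class names, highest
#'   priority first.
#' @export
default_hierarchy <- function() {
  c("feeding", "boom", "gulping", "shaking", "burst_swimming", "turning",
    "rolling", "listing", "backward_swimming", "forward_swimming",
    "gliding", "hovering", "resting")
}

check_hierarchy <- function(hierarchy) {
  if (!setequal(hierarchy, behavior_classes()$name) ||
      length(hierarchy) != 13L)
    stop("hierarchy must be a permutation of the 13 class names")
  if (match("boom", hierarchy) > match("forward_swimming", hierarchy))
    stop("hierarchy must rank boom above forward_swimming")
  hierarchy
}

#' Resolve simultaneous behaviors to a single class
#'
#' @param active Character vector of currently active behavior classes.
#' @param hierarchy Priority order, first wins; see [default_hierarchy()].
#' @return The single winning class name.
#' @export
resolve_label <- function(active, hierarchy = default_hierarchy()) {
  if (length(active) == 0L) stop("no active behavior to resolve")
  hit <- hierarchy[hierarchy %in% active]
  if (length(hit) == 0L) stop("active classes not found in hierarchy: ",
                              paste(active, collapse = ", "))
  hit[1L]
}

#' Read a behavior label file
#'
#' @param path CSV with columns `class`, `start_s`, `end_s` (half-open
#'   intervals in seconds from recording start).
#' @return A data.frame of label intervals.
#' @export
read_label_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("class", "start_s", "end_s")
  if (!all(need %in% names(dt)))
    stop("label file format error: need columns ", paste(need, collapse = ", "))
  iv <- as.data.frame(dt[, need, with = FALSE])
  if (any(iv$end_s <= iv$start_s)) stop("label intervals must have end_s > start_s")
  iv
}

#' Assign one behavior class per epoch
#'
#' An epoch's active set is the set of classes whose interval covers the
#' epoch midpoint; the labeling hierarchy resolves simultaneous behaviors.
#' Epochs covered by no interval are dropped (count recorded in the result).
#'
#' @param epochs List of epochs from [segment_epochs()].
#' @param intervals Data.frame of label intervals (`class`, `start_s`,
#'   `end_s`, half-open).
#' @param hierarchy Priority order; see [default_hierarchy()].
#' @return A `labeled_epochs` object: fields `epochs` (list), `class`
#'   (factor over the 13 ethogram classes), `augmented` (logical flags,
#'   all FALSE here) and `dropped` (number of unlabeled epochs discarded).
#' @export
label_epochs <- function(epochs, intervals, hierarchy = default_hierarchy()) {
  check_hierarchy(hierarchy)
  mids <- vapply(epochs, function(e) e$t0 + 0.5, numeric(1))
  lab <- character(length(epochs))
  for (i in seq_along(epochs)) {
    act <- unique(intervals$class[intervals$start_s <= mids[i] &
                                  mids[i] < intervals$end_s])
    lab[i] <- if (length(act)) resolve_label(act, hierarchy) else NA_character_
  }
  keep <- !is.na(lab)
  labeled_epochs(epochs[keep],
                 factor(lab[keep], levels = behavior_classes()$name),
                 dropped = sum(!keep))
}

#' Container for labeled epochs
#'
#' @param epochs List of `imu_epoch` objects.
#' @param class Factor of behavior classes, one per epoch.
#' @param augmented Logical flags marking augmentation products.
#' @param dropped Count of epochs discarded as unlabeled upstream.
#' @return A `labeled_epochs` object.
#' @export
labeled_epochs <- function(epochs, class,
                           augmented = rep(FALSE, length(epochs)),
                           dropped = 0L) {
  class <- factor(class, levels = behavior_classes()$name)
  stopifnot(length(epochs) == length(class),
            length(augmented) == length(epochs), !anyNA(class))
  structure(list(epochs = epochs, class = class,
                 augmented = augmented, dropped = as.integer(dropped)),
            class = "labeled_epochs")
}

#' @export
length.labeled_epochs <- function(x) length(x$epochs)

#' @export
`[.labeled_epochs` <- function(x, i) {
  labeled_epochs(x$epochs[i], x$class[i], x$augmented[i], dropped = x$dropped)
}

#' @export
print.labeled_epochs <- function(x, ...) {
  cat("labeled_epochs:", length(x), "epochs (", sum(x$augmented),
      "augmented,", x$dropped, "dropped upstream )\n")
  print(class_budget(x))
  invisible(x)
}

#' Per-class epoch counts
#'
#' Tabulates labeled seconds per behavior class, including the classes
#' excluded from training; the class budget of a deployment set.
#'
#' @param labeled A `labeled_epochs` object, or a factor/character vector of
#'   class labels.
#' @return Named integer vector over all 13 classes, summing to the number
#'   of labeled epochs.
#' @export
class_budget <- function(labeled) {
  cls <- if (inherits(labeled, "labeled_epochs")) labeled$class else labeled
  table(factor(cls, levels = behavior_classes()$name))
}

#' Drop the classes excluded from classifier training
#'
#' @param labeled A `labeled_epochs` object.
#' @return A `labeled_epochs` object containing only the nine retained
#'   classes.
#' @export
filter_training_classes <- function(labeled) {
  labeled[labeled$class %in% retained_classes()]
}
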