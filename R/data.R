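#' Per-fish labeled-second counts for each behavior class
#'
#' The published class budget of the six tag deployments: seconds of
#' labeled data each fish contributed to each of the 13 ethogram classes.
#' Used as the default class mixture of the simulator and for budget
#' arithmetic.
#'
#' @return Data.frame with columns `class`, `fish1`..`fish6` (NA where a
#'   fish never showed the behavior) and a `total` column.
#' @export
behavior_observation_counts <- function() {
  path <- system.file("extdata", "behavior_counts.csv",
                      package = "imubehave", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$total <- rowSums(df[, paste0("fish", 1:6)], na.rm = TRUE)
  df
}

#' Deployment summary of the six tagged fish
#'
#' Tagging dates, fish sizes, accelerometer sampling rate and approximate
#' tag retention duration per deployment.
#'
#' @return Data.frame, one row per deployment.
#' @export
deployment_summary <- function() {
  path <- system.file("extdata", "deployments.csv",
                      package = "imubehave", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
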