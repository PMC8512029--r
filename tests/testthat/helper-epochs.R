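# build a free-standing 1-s epoch from channel matrices (50 Hz default);
# the acc context defaults to the epoch itself (shrunken-window split)
make_epoch <- function(acc = NULL, gyro = NULL, mag = NULL,
                       pressure = 1013.25, pressure_next = 1013.25,
                       hz = 50L, seed = NULL) {
  gen <- function() matrix(rnorm(hz * 3), hz, 3)
  if (!is.null(seed)) set.seed(seed)
  acc <- acc %||% gen(); gyro <- gyro %||% gen(); mag <- mag %||% gen()
  structure(list(index = 1L, t0 = 0, acc = acc, gyro = gyro, mag = mag,
                 pressure = pressure, temperature = 26,
                 pressure_next = pressure_next, acc_context = acc,
                 context_start = 1L, acc_hz = hz),
            class = "imu_epoch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# labeled set of well-separated sinusoid "behaviors" for quick model tests:
# class k puts a tone of frequency f_k on a distinct axis
make_toy_labeled <- function(classes = c("resting", "hovering", "boom"),
                             n_per_class = 15L, seed = 1L) {
  set.seed(seed)
  freqs <- c(2, 6, 12)[seq_along(classes)]
  axis <- c(1L, 2L, 3L)[seq_along(classes)]
  eps <- list(); cls <- character()
  t <- (0:49) / 50
  for (i in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      acc <- matrix(rnorm(150, 0, 0.05), 50, 3)
      acc[, 3] <- acc[, 3] + 1
      acc[, axis[i]] <- acc[, axis[i]] +
        0.8 * sin(2 * pi * freqs[i] * t + runif(1, 0, 2 * pi))
      eps[[length(eps) + 1L]] <- make_epoch(
        acc = acc, gyro = matrix(rnorm(150, 0, 0.5), 50, 3),
        mag = matrix(rnorm(150, 0, 0.01), 50, 3) + rep(c(0.4, 0, 0.9), each = 50))
      cls <- c(cls, classes[i])
    }
  }
  labeled_epochs(eps, cls)
}
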