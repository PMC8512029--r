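#' Spectral input configuration
#'
#' Fixes the CNN input representation: each of the nine IMU channels of a
#' 1-s, 50 Hz epoch is zero-padded to `nfft` samples, Fourier transformed,
#' and the absolute values of the first `nfft / 2` bins kept, giving a
#' 256 x 9 matrix in fixed channel order (ax, ay, az, gx, gy, gz, mx, my,
#' mz). Optional per-bin, per-channel z-score normalization parameters are
#' fitted on training data only.
#'
#' @param nfft FFT length (bins kept = nfft / 2).
#' @param sample_hz Required channel rate.
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(nfft = 512L, sample_hz = 50L) {
  structure(list(nfft = as.integer(nfft), n_bins = as.integer(nfft) %/% 2L,
                 sample_hz = as.integer(sample_hz),
                 channels = c("ax", "ay", "az", "gx", "gy", "gz",
                              "mx", "my", "mz"),
                 norm = NULL), class = "spectral_config")
}

#' Build the 256 x 9 absolute-FFT input for one epoch
#'
#' @param epoch An `imu_epoch` whose nine IMU channels are at the
#'   configured rate (50 Hz).
#' @param cfg A [spectral_config()]. If it carries fitted normalization
#'   parameters they are applied (z-score per bin and channel).
#' @return Numeric matrix, `n_bins` x 9; non-negative when unnormalized.
#' @export
build_spectral_input <- function(epoch, cfg = spectral_config()) {
  if (nrow(epoch$acc) != cfg$sample_hz)
    stop("spectral input requires ", cfg$sample_hz,
         " Hz channels; acc epoch has ", nrow(epoch$acc), " samples")
  chans <- cbind(epoch$acc, epoch$gyro, epoch$mag)
  m <- apply(chans, 2, spectral_magnitude, nfft = cfg$nfft)
  colnames(m) <- cfg$channels
  if (!is.null(cfg$norm)) m <- (m - cfg$norm$mean) / cfg$norm$sd
  m
}

#' Spectral inputs for a set of epochs
#'
#' @param labeled A `labeled_epochs` object or list of epochs.
#' @param cfg A [spectral_config()].
#' @return Numeric array, `n_bins` x 9 x n_epochs.
#' @export
build_spectral_array <- function(labeled, cfg = spectral_config()) {
  eps <- if (inherits(labeled, "labeled_epochs")) labeled$epochs else labeled
  out <- vapply(eps, build_spectral_input, cfg = cfg,
                matrix(0, cfg$n_bins, 9L))
  array(out, dim = c(cfg$n_bins, 9L, length(eps)))
}

#' Fit per-bin z-score normalization on training inputs
#'
#' Stores per-channel, per-bin mean and standard deviation (floored at
#' 1e-8 so constant bins normalize to zero) for application at train and
#' inference time.
#'
#' @param inputs Array `n_bins` x 9 x n (from [build_spectral_array()]),
#'   n >= 2, unnormalized.
#' @param cfg A [spectral_config()].
#' @return `cfg` with the `norm` field filled.
#' @export
fit_normalizer <- function(inputs, cfg = spectral_config()) {
  stopifnot(length(dim(inputs)) == 3L, dim(inputs)[3] >= 2L)
  mu <- apply(inputs, c(1, 2), mean)
  sd <- pmax(apply(inputs, c(1, 2), stats::sd), 1e-8)
  cfg$norm <- list(mean = mu, sd = sd)
  cfg
}

#' Apply a fitted normalizer to a spectral array
#'
#' @param inputs Array `n_bins` x 9 x n, unnormalized.
#' @param cfg A [spectral_config()] with fitted `norm`.
#' @return Normalized array of the same shape.
#' @export
apply_normalizer <- function(inputs, cfg) {
  if (is.null(cfg$norm)) stop("normalizer not fitted")
  sweep(sweep(inputs, c(1, 2), cfg$norm$mean, "-"), c(1, 2), cfg$norm$sd, "/")
}
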