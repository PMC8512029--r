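#' The pinned 187-feature catalog
#'
#' The handcrafted feature set computed for every 1-s epoch, in fixed order:
#' \itemize{
#'   \item 10 time-domain statistics (mean, sd, min, max, median, skewness,
#'     kurtosis, median absolute deviation, inverse coefficient of
#'     variation, interquartile range) for each of the 9 IMU axes and for
#'     ODBA (100 features);
#'   \item signal magnitude area of the raw acceleration (1);
#'   \item mean q (vector norm) per sensor (3);
#'   \item circular variances of inclination and azimuth per sensor (6);
#'   \item pairwise accelerometer-axis correlations (3);
#'   \item vertical velocity from the pressure channel (1);
#'   \item 8 spectral statistics (power, mean, sd, median, min, max,
#'     entropy, energy) per IMU axis (72);
#'   \item ODBA spectral energy (1).
#' }
#'
#' @return A data.frame with columns `name`, `signal`, `domain`,
#'   `statistic`; exactly 187 rows, names unique.
#' @export
feature_catalog <- function() {
  axes <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
            "mag_x", "mag_y", "mag_z")
  tstats <- c("mean", "sd", "min", "max", "median", "skewness", "kurtosis",
              "mad", "invcov", "iqr")
  fstats <- c("power", "mean", "sd", "median", "min", "max", "entropy",
              "energy")
  rows <- list()
  for (s in c(axes, "odba")) for (st in tstats)
    rows[[length(rows) + 1L]] <- c(paste(s, st, sep = "_"), s, "time", st)
  rows[[length(rows) + 1L]] <- c("sma", "acc", "time", "sma")
  for (s in c("acc", "gyro", "mag"))
    rows[[length(rows) + 1L]] <- c(paste0(s, "_q_mean"), s, "time", "q_mean")
  for (s in c("acc", "gyro", "mag")) for (st in c("cv_inclination", "cv_azimuth"))
    rows[[length(rows) + 1L]] <- c(paste(s, st, sep = "_"), s, "time", st)
  for (pr in c("xy", "xz", "yz"))
    rows[[length(rows) + 1L]] <- c(paste0("acc_corr_", pr), "acc", "time",
                                   paste0("corr_", pr))
  rows[[length(rows) + 1L]] <- c("vertical_velocity", "pressure", "time",
                                 "vertical_velocity")
  for (s in axes) for (st in fstats)
    rows[[length(rows) + 1L]] <- c(paste(s, "spec", st, sep = "_"), s,
                                   "frequency", st)
  rows[[length(rows) + 1L]] <- c("odba_spec_energy", "odba", "frequency",
                                 "energy")
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "signal", "domain", "statistic")
  out
}

#' Split total acceleration into static and dynamic components
#'
#' The gravitational (static) component is estimated per axis by a centered
#' 3-s running mean of the total acceleration; the dynamic component is the
#' sample-wise remainder. Near the series edges the averaging window
#' shrinks to the available samples. Window convention: for an even window
#' of w samples, sample i averages indices `i - w/2` through `i + w/2 - 1`
#' (clipped).
#'
#' @param acc Numeric matrix, n x 3, total acceleration (g). When computing
#'   epoch features this is the 3-s context around the epoch.
#' @param hz Sampling rate of `acc`.
#' @param window_s Running-mean width in seconds.
#' @return List with matrices `static` and `dynamic` (same shape as `acc`);
#'   `static + dynamic == acc` sample-wise.
#' @export
static_dynamic_split <- function(acc, hz = 50L, window_s = 3) {
  acc <- as.matrix(acc)
  n <- nrow(acc)
  w <- round(window_s * hz)
  i <- seq_len(n)
  lo <- pmax(1L, i - w %/% 2L)
  hi <- pmin(n, i + w %/% 2L - 1L)
  cs <- apply(acc, 2, function(x) cumsum(c(0, x)))
  static <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  list(static = static, dynamic = acc - static)
}

#' Overall dynamic body acceleration
#'
#' Per-sample sum of the absolute dynamic (gravity-removed) acceleration
#' over the three axes; a standard proxy for movement intensity.
#'
#' @param dynamic Numeric matrix, n x 3, dynamic acceleration.
#' @return Non-negative numeric vector of length n.
#' @export
odba <- function(dynamic) rowSums(abs(as.matrix(dynamic)))

#' Ten time-domain summary statistics
#'
#' Mean, standard deviation (sample), min, max, median, skewness, kurtosis
#' (moment-based, non-excess), median absolute deviation (unscaled),
#' inverse coefficient of variation (mean/sd), and interquartile range
#' (linear-interpolation quartiles, type 7). Zero-variance input yields 0
#' for skewness, kurtosis and mean/sd.
#'
#' @param x Numeric vector with at least 2 samples.
#' @return Named numeric vector of length 10.
#' @export
time_domain_stats <- function(x) {
  if (length(x) < 2L) stop("insufficient data: need at least 2 samples")
  mu <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  } else skew <- kurt <- 0
  c(mean = mu, sd = s, min = min(x), max = max(x), median = stats::median(x),
    skewness = skew, kurtosis = kurt,
    mad = stats::median(abs(x - stats::median(x))),
    invcov = if (s > 0) mu / s else 0,
    iqr = stats::IQR(x, type = 7))
}

#' Signal magnitude area
#'
#' Mean over the epoch of the per-sample sum of absolute raw acceleration
#' across the three axes (per-epoch normalization by sample count keeps the
#' value comparable across sampling rates).
#'
#' @param acc Numeric matrix, n x 3, raw acceleration.
#' @return Scalar, non-negative.
#' @export
signal_magnitude_area <- function(acc) mean(rowSums(abs(as.matrix(acc))))

#' Per-sample vector norm of a tri-axial sensor
#'
#' @param m Numeric matrix, n x 3.
#' @return Numeric vector, `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
q_norm <- function(m) sqrt(rowSums(as.matrix(m)^2))

#' Circular variances of sensor inclination and azimuth
#'
#' Inclination is `acos(z / q)` and azimuth `atan2(y, x)` per sample;
#' circular variance is one minus the mean resultant length, in `[0, 1]`.
#' Samples with zero norm carry no direction and are dropped; an all-zero
#' epoch returns `c(0, 0)` with attribute `degenerate = TRUE`.
#'
#' @param m Numeric matrix, n x 3.
#' @return Named vector `c(cv_inclination, cv_azimuth)`.
#' @export
circular_variances <- function(m) {
  m <- as.matrix(m)
  q <- q_norm(m)
  ok <- q > 0
  if (!any(ok)) {
    out <- c(cv_inclination = 0, cv_azimuth = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cv <- function(theta) {
    1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  }
  incl <- acos(pmin(1, pmax(-1, m[ok, 3] / q[ok])))
  az <- atan2(m[ok, 2], m[ok, 1])
  c(cv_inclination = max(0, min(1, cv(incl))),
    cv_azimuth = max(0, min(1, cv(az))))
}

#' Pairwise Pearson correlations between accelerometer axes
#'
#' @param acc Numeric matrix, n x 3 (n >= 2). A zero-variance axis yields 0
#'   for the correlations involving it.
#' @return Named vector `c(r_xy, r_xz, r_yz)`.
#' @export
acc_pairwise_correlations <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2L) stop("insufficient data for correlations")
  v <- apply(acc, 2, stats::var)
  r <- function(i, j) if (v[i] > 0 && v[j] > 0) stats::cor(acc[, i], acc[, j]) else 0
  c(r_xy = r(1, 2), r_xz = r(1, 3), r_yz = r(2, 3))
}

# seawater hydrostatic factor: Pa per metre of depth (rho = 1025 kg/m^3)
.pa_per_m <- 1025 * 9.81

#' Vertical velocity from the pressure channel
#'
#' Depth is hydrostatic, `depth = 100 * (P - P_surface) / (rho * g)` with
#' P in mbar and rho = 1025 kg/m^3; vertical velocity over a 1-s epoch is
#' the depth difference between the epoch's two boundary pressure samples
#' (positive = descending). A missing boundary yields 0.
#'
#' @param p0 Pressure (mbar) at the epoch start.
#' @param p1 Pressure (mbar) one second later (`NA` if the recording ends).
#' @return Vertical velocity in m/s.
#' @export
vertical_velocity <- function(p0, p1) {
  if (is.na(p0) || is.na(p1)) return(0)
  (p1 - p0) * 100 / .pa_per_m
}

#' Eight spectral summary statistics of a 1-s signal
#'
#' The signal is zero-padded to `nfft`, Fourier transformed, and the
#' one-sided magnitude spectrum (bins 0 to nfft/2 - 1) summarized: energy is
#' the sum of squared magnitudes, power is energy per time-domain sample,
#' mean/sd/median/min/max are over the non-DC bins, and entropy is the
#' Shannon entropy (nats) of the magnitude spectrum normalized to sum 1.
#' An all-zero signal returns all zeros (entropy 0 by convention).
#'
#' @param x Numeric vector (one epoch of one channel).
#' @param nfft FFT length; the epoch is zero-padded to this.
#' @return Named numeric vector of length 8.
#' @export
frequency_domain_stats <- function(x, nfft = 512L) {
  zero <- c(power = 0, mean = 0, sd = 0, median = 0, min = 0, max = 0,
            entropy = 0, energy = 0)
  if (all(x == 0)) return(zero)
  mag <- spectral_magnitude(x, nfft)
  en <- sum(mag^2)
  p <- mag / sum(mag)
  p <- p[p > 0]
  bins <- mag[-1L]  # DC excluded from the order statistics
  c(power = en / length(x), mean = mean(bins), sd = stats::sd(bins),
    median = stats::median(bins), min = min(bins), max = max(bins),
    entropy = -sum(p * log(p)), energy = en)
}

# one-sided magnitude spectrum of a zero-padded signal (bins 0..nfft/2-1)
spectral_magnitude <- function(x, nfft = 512L) {
  n <- length(x)
  if (n > nfft) stop("signal longer than nfft")
  abs(stats::fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2L)]
}

#' Extract the 187-feature vector for one epoch
#'
#' Computes every entry of [feature_catalog()] from the epoch's channel
#' blocks. The static/dynamic split uses the epoch's stored 3-s
#' acceleration context (shrunk at recording edges); all other statistics
#' use the 1-s blocks. Degenerate inputs (zero variance, all-zero sensors,
#' missing pressure boundary) follow the catalog's substitution rules, so
#' the result is always finite.
#'
#' @param epoch An `imu_epoch` from [segment_epochs()].
#' @return Named numeric vector of length 187 in catalog order.
#' @export
extract_features <- function(epoch) {
  hz <- epoch$acc_hz %||% nrow(epoch$acc)
  ctx <- epoch$acc_context %||% epoch$acc
  cs <- epoch$context_start %||% 1L
  dyn <- static_dynamic_split(ctx, hz = hz)$dynamic
  od <- odba(dyn[cs:(cs + nrow(epoch$acc) - 1L), , drop = FALSE])

  axes <- cbind(epoch$acc, epoch$gyro, epoch$mag)
  td <- c(as.numeric(apply(axes, 2, time_domain_stats)),
          time_domain_stats(od))
  sensors <- list(acc = epoch$acc, gyro = epoch$gyro, mag = epoch$mag)
  qm <- vapply(sensors, function(m) mean(q_norm(m)), numeric(1))
  cv <- as.numeric(vapply(sensors, circular_variances, numeric(2)))
  fd <- as.numeric(apply(axes, 2, frequency_domain_stats))
  vals <- c(td,
            signal_magnitude_area(epoch$acc),
            qm, cv,
            acc_pairwise_correlations(epoch$acc),
            vertical_velocity(epoch$pressure,
                              epoch$pressure_next %||% NA_real_),
            fd,
            frequency_domain_stats(od)[["energy"]])
  names(vals) <- feature_catalog()$name
  stopifnot(length(vals) == 187L, all(is.finite(vals)))
  vals
}

#' Feature matrix for a set of labeled epochs
#'
#' @param labeled A `labeled_epochs` object (or plain list of epochs).
#' @return Numeric matrix, one row per epoch, 187 named columns.
#' @export
extract_feature_matrix <- function(labeled) {
  eps <- if (inherits(labeled, "labeled_epochs")) labeled$epochs else labeled
  t(vapply(eps, extract_features, numeric(187L)))
}
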