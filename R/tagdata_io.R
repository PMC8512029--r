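#' Construct an IMU recording
#'
#' Bundles the time-aligned sensor channels of one tag deployment. Channels
#' run at their native rates: acceleration at 50 or 200 Hz, gyroscope and
#' magnetometer at 50 Hz, pressure and temperature at 1 Hz. All channel
#' lengths must be consistent with a shared recording duration (tolerance of
#' one sample per channel) and contain no missing values; gap handling
#' happens at ingestion, not here.
#'
#' @param deployment_id Character identifier for the deployment.
#' @param acc Numeric matrix, n x 3, total acceleration in g (columns x, y, z).
#' @param gyro Numeric matrix, n x 3, angular velocity in deg/s.
#' @param mag Numeric matrix, n x 3, calibrated magnetic field (arbitrary units).
#' @param pressure Numeric vector, 1 Hz, in mbar.
#' @param temperature Numeric vector, 1 Hz, in degrees C.
#' @param acc_hz Accelerometer sampling rate; 50 or 200.
#' @param start_time Recording start, seconds (kept as metadata; all
#'   per-sample times are seconds from start).
#'
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(deployment_id, acc, gyro, mag, pressure, temperature,
                          acc_hz = 50L, start_time = 0) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  if (!acc_hz %in% c(50L, 200L))
    stop("acc_hz must be 50 or 200, got ", acc_hz)
  for (nm in c("acc", "gyro", "mag"))
    if (ncol(get(nm)) != 3L) stop(nm, " must have 3 columns")
  chans <- list(acc = nrow(acc) / acc_hz, gyro = nrow(gyro) / 50,
                mag = nrow(mag) / 50, pressure = length(pressure),
                temperature = length(temperature))
  durs <- unlist(chans)
  # per-channel tolerance: one sample at that channel's rate
  tol <- c(acc = 1 / acc_hz, gyro = 1 / 50, mag = 1 / 50,
           pressure = 1, temperature = 1)
  if (max(durs) - min(durs) > max(tol) + 1e-9)
    stop("channel durations inconsistent: ",
         paste(sprintf("%s=%.2fs", names(durs), durs), collapse = ", "))
  vals <- c(acc, gyro, mag, pressure, temperature)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("recording contains missing or non-finite values after ingestion")
  structure(list(deployment_id = as.character(deployment_id),
                 acc = unname(acc), gyro = unname(gyro), mag = unname(mag),
                 pressure = as.numeric(pressure),
                 temperature = as.numeric(temperature),
                 acc_hz = as.integer(acc_hz), gyro_hz = 50L, mag_hz = 50L,
                 start_time = start_time),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat("IMU recording '", x$deployment_id, "'\n", sep = "")
  cat(sprintf("  duration: %.1f s  (acc %d Hz, gyro/mag 50 Hz, pressure/temp 1 Hz)\n",
              recording_duration(x), x$acc_hz))
  cat(sprintf("  samples: acc %d, gyro %d, mag %d, pressure %d\n",
              nrow(x$acc), nrow(x$gyro), nrow(x$mag), length(x$pressure)))
  invisible(x)
}

#' Recording duration in seconds
#'
#' The shared duration of a recording, taken as the minimum duration implied
#' by any channel (channels may differ by at most one sample).
#'
#' @param rec An `imu_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  min(nrow(rec$acc) / rec$acc_hz, nrow(rec$gyro) / 50, nrow(rec$mag) / 50,
      length(rec$pressure), length(rec$temperature))
}

tag_columns <- c("time", "ax", "ay", "az", "gx", "gy", "gz",
                 "mx", "my", "mz", "pressure", "temp")

#' Read a raw tag export
#'
#' Reads a delimited tag export with one row per accelerometer sample and the
#' slower channels present on their own sample rows (blank elsewhere).
#' Expected header: `time, ax, ay, az, gx, gy, gz, mx, my, mz, pressure, temp`.
#' Timestamps are converted to seconds from start. Short dropouts (up to
#' 0.2 s per channel) are filled by linear interpolation; anything longer is
#' rejected as a data-quality error naming the interval.
#'
#' @param path Path to the CSV export.
#' @param metadata List with at least `acc_hz` (50 or 200); optional
#'   `deployment_id` (defaults to the file name).
#' @param max_gap_s Longest per-channel dropout that is interpolated rather
#'   than rejected, in seconds.
#' @return An [imu_recording()].
#' @export
read_tag_csv <- function(path, metadata = list(acc_hz = 50L),
                         max_gap_s = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"))
  missing_cols <- setdiff(tag_columns, names(dt))
  if (length(missing_cols))
    stop("tag file format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  acc_hz <- as.integer(metadata$acc_hz %||% 50L)
  id <- metadata$deployment_id %||% sub("\\.[^.]*$", "", basename(path))
  n <- nrow(dt)
  tvec <- dt$time - dt$time[1]

  # pull one channel off the master (acc-rate) grid and repair short gaps
  take <- function(col, rate) {
    step <- acc_hz %/% rate
    pos <- seq(1L, n, by = step)
    grid <- (seq_along(pos) - 1L) / rate
    v <- dt[[col]][pos]
    if (!anyNA(v)) return(v)
    ok <- !is.na(v)
    if (sum(ok) < 2L) stop("data-quality error: channel ", col, " is empty")
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(!runs$values)) {
      gap <- runs$lengths[j] / rate
      if (gap > max_gap_s + 1e-9)
        stop(sprintf(
          "data-quality error: %s has a %.2f s gap in [%.3f, %.3f] s",
          col, gap, grid[starts[j]], grid[ends[j]]))
    }
    stats::approx(grid[ok], v[ok], xout = grid, rule = 2)$y
  }
  acc <- cbind(take("ax", acc_hz), take("ay", acc_hz), take("az", acc_hz))
  gyro <- cbind(take("gx", 50L), take("gy", 50L), take("gz", 50L))
  mag <- cbind(take("mx", 50L), take("my", 50L), take("mz", 50L))
  imu_recording(id, acc, gyro, mag,
                pressure = take("pressure", 1L),
                temperature = take("temp", 1L),
                acc_hz = acc_hz, start_time = dt$time[1])
}

#' Write a recording in the raw tag export format
#'
#' Inverse of [read_tag_csv()]: one row per accelerometer sample, slower
#' channels on their sample rows, blanks elsewhere. Values are written with
#' 17 significant digits so a write/read round trip is value-identical.
#'
#' @param rec An `imu_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_csv <- function(rec, path) {
  n <- nrow(rec$acc)
  hz <- rec$acc_hz
  fmt <- function(x) sprintf("%.17g", x)
  col <- function(v, rate) {
    out <- rep("", n)
    pos <- seq(1L, by = hz %/% rate, length.out = length(v))
    pos <- pos[pos <= n]
    out[pos] <- fmt(v[seq_along(pos)])
    out
  }
  dt <- data.table::data.table(
    time = fmt(rec$start_time + (seq_len(n) - 1) / hz),
    ax = fmt(rec$acc[, 1]), ay = fmt(rec$acc[, 2]), az = fmt(rec$acc[, 3]),
    gx = col(rec$gyro[, 1], 50L), gy = col(rec$gyro[, 2], 50L),
    gz = col(rec$gyro[, 3], 50L),
    mx = col(rec$mag[, 1], 50L), my = col(rec$mag[, 2], 50L),
    mz = col(rec$mag[, 3], 50L),
    pressure = col(rec$pressure, 1L), temp = col(rec$temperature, 1L))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Decimate the accelerometer to the common analysis rate
#'
#' Deployments record acceleration at 50 or 200 Hz while the gyroscope and
#' magnetometer always run at 50 Hz, so analysis uses a common 50 Hz rate.
#' A 200 Hz accelerometer is low-pass filtered (zero-phase Butterworth,
#' cutoff 0.4 x target rate) before keeping every k-th sample; 50 Hz
#' channels pass through untouched. The channel mean is removed before
#' filtering and restored afterwards, so constant signals are preserved
#' exactly.
#'
#' @param rec An `imu_recording`.
#' @param target_hz Target rate; must divide the source accelerometer rate.
#' @return An `imu_recording` with `acc_hz = target_hz`.
#' @export
resample_to_common_rate <- function(rec, target_hz = 50L) {
  if (rec$acc_hz == target_hz) return(rec)
  if (rec$acc_hz %% target_hz != 0L)
    stop("unsupported rate: ", target_hz, " does not divide ", rec$acc_hz)
  k <- rec$acc_hz %/% target_hz
  bf <- signal::butter(6, 0.4 * target_hz / (rec$acc_hz / 2), type = "low")
  acc <- apply(rec$acc, 2, function(x) {
    mu <- mean(x)
    xf <- zerophase_filter(bf, x - mu) + mu
    xf[seq(1L, length(xf), by = k)]
  })
  imu_recording(rec$deployment_id, acc, rec$gyro, rec$mag, rec$pressure,
                rec$temperature, acc_hz = as.integer(target_hz),
                start_time = rec$start_time)
}

# forward-backward filtering with odd-reflection padding to suppress edge
# transients (signal::filtfilt uses zero initial conditions and no padding)
zerophase_filter <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 300L)
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xe <- c(pre, x, post)
  y <- signal::filtfilt(bf, xe)
  y[(np + 1L):(np + n)]
}

#' Cut a recording into contiguous 1-s epochs
#'
#' Behavior labels attach to whole seconds of data, so the recording is cut
#' into contiguous, non-overlapping half-open windows `[t, t+1)`. The
#' trailing partial second is dropped. Each epoch carries its native-rate
#' sample blocks plus a centered 3-s acceleration context (clipped at the
#' recording edges) used by the static/dynamic split, and the pressure
#' sample at the next epoch boundary for vertical velocity.
#'
#' @param rec An `imu_recording`.
#' @return A list of `imu_epoch` objects (empty, with a warning, if the
#'   recording is shorter than 1 s).
#' @export
segment_epochs <- function(rec) {
  dur <- recording_duration(rec)
  n_ep <- floor(dur + 1e-9)
  if (n_ep < 1L) {
    warning("recording shorter than 1 s; no epochs")
    return(list())
  }
  hz <- rec$acc_hz
  lapply(seq_len(n_ep) - 1L, function(i) {
    a0 <- i * hz + 1L
    ctx0 <- max(1L, a0 - hz)
    ctx1 <- min(nrow(rec$acc), a0 + 2L * hz - 1L)
    structure(list(
      index = i + 1L, t0 = i,
      acc = rec$acc[a0:(a0 + hz - 1L), , drop = FALSE],
      gyro = rec$gyro[(i * 50L + 1L):(i * 50L + 50L), , drop = FALSE],
      mag = rec$mag[(i * 50L + 1L):(i * 50L + 50L), , drop = FALSE],
      pressure = rec$pressure[i + 1L],
      temperature = rec$temperature[i + 1L],
      pressure_next = if (i + 2L <= length(rec$pressure))
        rec$pressure[i + 2L] else NA_real_,
      acc_context = rec$acc[ctx0:ctx1, , drop = FALSE],
      context_start = a0 - ctx0 + 1L,
      acc_hz = hz), class = "imu_epoch")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
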