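#' Kinematic signature parameters for the simulated behaviors
#'
#' Defines, per ethogram class, the waveform the simulator writes onto the
#' nine IMU channels: lateral sway amplitude/frequency for swimming gaits
#' (tail-beat visible on lateral acceleration and yaw gyroscope), static
#' posture offsets (resting is gravity-dominated and near-motionless),
#' brief pulse transients (boom, gulping, feeding), broadband
#' high-frequency content (shaking, burst swimming), sustained yaw with
#' heading drift (turning), a sub-45-degree roll offset (listing, with
#' rolling going beyond it), plus per-channel noise levels, target depths
#' and bout-duration ranges. These are test-fixture parameters mirroring
#' the qualitative ethogram descriptions, not biological measurements.
#'
#' @return Named list of per-class parameter lists.
#' @export
behavior_signature_spec <- function() {
  sig <- function(sway_amp = 0, sway_f = c(0, 0), gyro_amp = 0,
                  pulse_f = 0, pulse_amp = 0, pulse_len = 0,
                  broadband = 0, yaw_rate = 0, roll_deg = 0, pitch_deg = 0,
                  depth = 2, dur = c(2, 6), phase_sign = 1)
    list(sway_amp = sway_amp, sway_f = sway_f, gyro_amp = gyro_amp,
         pulse_f = pulse_f, pulse_amp = pulse_amp, pulse_len = pulse_len,
         broadband = broadband, yaw_rate = yaw_rate, roll_deg = roll_deg,
         pitch_deg = pitch_deg, depth = depth, dur = dur,
         phase_sign = phase_sign)
  list(
    forward_swimming = sig(sway_amp = 0.25, sway_f = c(1.1, 1.6),
                           gyro_amp = 30, yaw_rate = 5, dur = c(3, 10)),
    backward_swimming = sig(sway_amp = 0.12, sway_f = c(0.5, 0.75),
                            gyro_amp = 12, phase_sign = -1, dur = c(2, 6)),
    burst_swimming = sig(sway_amp = 0.6, sway_f = c(2.5, 3.5),
                         gyro_amp = 60, broadband = 0.1, dur = c(1, 3)),
    gliding = sig(pitch_deg = -10, depth = 1.5, dur = c(2, 5)),
    hovering = sig(sway_amp = 0.03, sway_f = c(0.25, 0.35), gyro_amp = 2,
                   depth = 2.5, dur = c(5, 20)),
    resting = sig(depth = 4.5, dur = c(5, 20)),
    boom = sig(pulse_f = 8, pulse_amp = 0.5, pulse_len = 0.3,
               dur = c(2, 4)),
    gulping = sig(pulse_f = 4.5, pulse_amp = 0.25, pulse_len = 0.2,
                  dur = c(2, 4)),
    feeding = sig(pulse_f = 3, pulse_amp = 0.4, pulse_len = 0.5,
                  sway_amp = 0.1, sway_f = c(1, 1.4), dur = c(2, 5)),
    turning = sig(yaw_rate = 45, gyro_amp = 5, sway_amp = 0.05,
                  sway_f = c(0.8, 1.2), dur = c(2, 5)),
    listing = sig(roll_deg = 30, dur = c(2, 6)),
    rolling = sig(roll_deg = 70, gyro_amp = 10, dur = c(2, 4)),
    shaking = sig(broadband = 0.25, pulse_f = 15, pulse_amp = 0.2,
                  pulse_len = 1, gyro_amp = 40, dur = c(1, 3)),
    noise = list(acc = 0.02, gyro = 1.5, mag = 0.01))
}

#' Simulation configuration
#'
#' @param duration_s Deployment length in seconds (>= 60).
#' @param acc_hz Accelerometer rate, 50 or 200.
#' @param mixture Named numeric vector of target time proportions per
#'   class; defaults to the observed class budget of the six deployments
#'   ([behavior_observation_counts()] totals). Must sum to 1 (normalized
#'   if not).
#' @param seed Integer seed.
#' @param deployment_id Identifier written into the recording.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(duration_s = 600, acc_hz = 50L,
                              mixture = NULL, seed = 1L,
                              deployment_id = "synthetic") {
  if (duration_s < 60) stop("duration_s must be >= 60")
  if (is.null(mixture)) {
    bc <- behavior_observation_counts()
    mixture <- stats::setNames(bc$total, bc$class)
  }
  mixture <- mixture / sum(mixture)
  structure(list(duration_s = duration_s, acc_hz = as.integer(acc_hz),
                 mixture = mixture, seed = as.integer(seed),
                 deployment_id = deployment_id),
            class = "simulation_config")
}

# synthesize the channel blocks of one bout; `state` carries heading (deg),
# depth (m) and the running time offset between bouts
simulate_bout <- function(class, dur, spec, state, acc_hz, noise) {
  p <- spec[[class]]
  na <- round(dur * acc_hz); ng <- round(dur * 50)
  ta <- (seq_len(na) - 1) / acc_hz
  tg <- (seq_len(ng) - 1) / 50
  f <- stats::runif(1, p$sway_f[1], max(p$sway_f))
  phi <- stats::runif(1, 0, 2 * pi)
  roll <- p$roll_deg * pi / 180 * sample(c(-1, 1), 1)
  pitch <- p$pitch_deg * pi / 180

  sway <- function(t) p$sway_amp * sin(2 * pi * f * t + phi)
  pulse <- function(t) {
    if (p$pulse_amp == 0) return(numeric(length(t)))
    out <- numeric(length(t))
    for (s in 0:(ceiling(dur) - 1)) {          # one transient per second
      t0 <- s + stats::runif(1, 0.2, 0.6)
      w <- t >= t0 & t < t0 + p$pulse_len
      out[w] <- out[w] + p$pulse_amp *
        sin(2 * pi * p$pulse_f * (t[w] - t0)) * exp(-(t[w] - t0) * 6)
    }
    out
  }
  grav <- c(-sin(pitch), sin(roll) * cos(pitch), cos(roll) * cos(pitch))
  acc <- cbind(grav[1] + pulse(ta) + p$broadband * stats::rnorm(na),
               grav[2] + sway(ta) + p$broadband * stats::rnorm(na),
               grav[3] + 0.3 * pulse(ta) + 0.5 * p$broadband * stats::rnorm(na)) +
    matrix(stats::rnorm(3 * na, 0, noise$acc), na)

  yaw <- p$yaw_rate * sample(c(-1, 1), 1)
  gyro <- cbind(p$gyro_amp * 0.2 * sin(2 * pi * f * tg + phi),
                p$gyro_amp * 0.2 * cos(2 * pi * f * tg + phi),
                yaw + p$phase_sign * p$gyro_amp * sin(2 * pi * f * tg + phi)) +
    matrix(stats::rnorm(3 * ng, 0, noise$gyro), ng)

  psi <- (state$heading + yaw * tg) * pi / 180
  mag <- cbind(0.4 * cos(psi), 0.4 * sin(psi),
               0.9 + 0.2 * sin(roll)) +
    matrix(stats::rnorm(3 * ng, 0, noise$mag), ng)

  depth_t <- state$depth + (p$depth - state$depth) * (1 - exp(-tg / 3))
  state$heading <- (state$heading + yaw * dur) %% 360
  state$depth <- min(5, max(0.5, depth_t[ng]))
  list(acc = acc, gyro = gyro, mag = mag,
       depth_grid = depth_t, tg = tg, state = state)
}

#' Simulate one labeled tag deployment
#'
#' Generates a seeded 9-channel IMU recording plus its label intervals.
#' Bout classes are scheduled by a deficit rule so realized time
#' proportions track the configured mixture closely; bout durations and
#' waveform parameters are drawn per bout. Channels are built as a gravity
#' (posture) projection plus the class waveform plus Gaussian sensor
#' noise; the pressure channel follows a shallow (< 5 m) depth track
#' consistent with each class.
#'
#' @param cfg A [simulation_config()].
#' @param spec A [behavior_signature_spec()].
#' @return List with `recording` (an [imu_recording()]) and `intervals`
#'   (data.frame of label intervals exactly covering the bouts).
#' @export
simulate_deployment <- function(cfg = simulation_config(),
                                spec = behavior_signature_spec()) {
  noise <- spec$noise
  classes <- names(cfg$mixture)[cfg$mixture > 0]
  target <- cfg$mixture[classes] / sum(cfg$mixture[classes])
  with_seed(cfg$seed, {
    state <- list(heading = stats::runif(1, 0, 360), depth = 2)
    acc <- gyro <- mag <- dep <- iv <- list()
    accrued <- stats::setNames(numeric(length(classes)), classes)
    t <- 0
    while (t < cfg$duration_s) {
      cl <- classes[which.max(target * (t + 10) - accrued)]
      dr <- spec[[cl]]$dur
      dur <- round(stats::runif(1, dr[1], dr[2]))
      dur <- min(dur, ceiling(cfg$duration_s - t))
      b <- simulate_bout(cl, dur, spec, state, cfg$acc_hz, noise)
      state <- b$state
      k <- length(iv) + 1L
      acc[[k]] <- b$acc; gyro[[k]] <- b$gyro; mag[[k]] <- b$mag
      dep[[k]] <- b$depth_grid[seq(1, length(b$tg), by = 50)]
      iv[[k]] <- data.frame(class = cl, start_s = t, end_s = t + dur)
      accrued[cl] <- accrued[cl] + dur
      t <- t + dur
    }
    acc <- do.call(rbind, acc); gyro <- do.call(rbind, gyro)
    mag <- do.call(rbind, mag)
    depth_1hz <- unlist(dep)
    pressure <- 1013.25 + depth_1hz * .pa_per_m / 100
    temperature <- 26 + 0.3 * sin(seq_along(depth_1hz) / 600) +
      stats::rnorm(length(depth_1hz), 0, 0.02)
    list(recording = imu_recording(cfg$deployment_id, acc, gyro, mag,
                                   pressure, temperature,
                                   acc_hz = cfg$acc_hz),
         intervals = do.call(rbind, iv))
  })
}

#' Build the synthetic classification benchmark
#'
#' The default benchmark holds `n_per_class` labeled 1-s epochs for each of
#' the nine retained behavior classes, generated from per-class simulated
#' deployments with well-separated kinematic signatures, split into
#' stratified train/test sets. The `"imbalanced"` variant instead draws a
#' class budget proportional to the observed deployment budget (hovering
#' modal), with a floor so every class remains usable.
#'
#' @param seed Integer seed.
#' @param n_per_class Epochs per class (balanced variant).
#' @param train_frac Fraction of each class assigned to the training set.
#' @param variant `"balanced"` or `"imbalanced"`.
#' @param n_total Approximate total epochs of the imbalanced variant.
#' @return List with `train` and `test` (`labeled_epochs` objects).
#' @export
benchmark_dataset <- function(seed = 1L, n_per_class = 200L,
                              train_frac = 0.8,
                              variant = c("balanced", "imbalanced"),
                              n_total = 2000L) {
  variant <- match.arg(variant)
  classes <- retained_classes()
  if (variant == "balanced") {
    n_c <- stats::setNames(rep(n_per_class, length(classes)), classes)
  } else {
    bc <- behavior_observation_counts()
    tot <- stats::setNames(bc$total, bc$class)[classes]
    n_c <- round(n_total * tot / sum(tot))
    n_c[n_c < 10L] <- 10L  # floor keeps rare classes usable
  }
  eps <- list(); cls <- character()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    cfg <- simulation_config(duration_s = max(60, n_c[[cl]] + 5),
                             mixture = stats::setNames(1, cl),
                             seed = seed + 101L * i,
                             deployment_id = paste0("bench_", cl))
    sim <- simulate_deployment(cfg)
    lab <- label_epochs(segment_epochs(sim$recording), sim$intervals)
    keep <- which(lab$class == cl)[seq_len(n_c[[cl]])]
    eps <- c(eps, lab$epochs[keep])
    cls <- c(cls, rep(cl, length(keep)))
  }
  all <- labeled_epochs(eps, cls)
  idx_tr <- with_seed(seed + 9999L,
    unlist(lapply(split(seq_along(cls), cls), function(ix)
      sample(ix, round(train_frac * length(ix))))))
  list(train = all[sort(idx_tr)],
       test = all[setdiff(seq_along(cls), sort(idx_tr))])
}
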