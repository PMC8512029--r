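#' Augmentation configuration
#'
#' Hyper-parameters for the three seeded time-domain augmentation
#' operators used to grow minority behavior classes: additive Gaussian
#' jitter (sigma constrained to `[0.01, 0.2]`), global magnitude scaling by
#' one draw of `N(1, sigma^2)` per sensor, and magnitude warping by a cubic
#' spline through `N(1, sigma^2)` knot values.
#'
#' @param jitter_sigma Jitter noise sd, in `[0.01, 0.2]`.
#' @param scale_sigma Scaling sd (> 0).
#' @param warp_sigma Warp knot sd (> 0).
#' @param warp_knots Number of spline knots (>= 2).
#' @param seed Integer seed for the augmentation stream.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(jitter_sigma = 0.05, scale_sigma = 0.1,
                                warp_sigma = 0.2, warp_knots = 4L,
                                seed = 1L) {
  if (jitter_sigma < 0.01 || jitter_sigma > 0.2)
    stop("jitter_sigma must lie in [0.01, 0.2]")
  if (scale_sigma <= 0 || warp_sigma <= 0) stop("sigmas must be positive")
  if (warp_knots < 2L) stop("warp_knots must be >= 2")
  structure(list(jitter_sigma = jitter_sigma, scale_sigma = scale_sigma,
                 warp_sigma = warp_sigma, warp_knots = as.integer(warp_knots),
                 seed = as.integer(seed)), class = "augmentation_config")
}

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Jitter: add Gaussian noise to a signal
#'
#' Adds independent `N(0, sigma^2)` noise to every sample.
#'
#' @param x Numeric vector or matrix (noise is independent per element).
#' @param sigma Noise standard deviation (>= 0; 0 is the identity).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Same shape as `x`.
#' @export
jitter_signal <- function(x, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  with_seed(seed, x + stats::rnorm(length(x), 0, sigma))
}

#' Magnitude scaling: multiply a signal by one random scalar
#'
#' Draws a single `gamma ~ N(1, sigma^2)` per call and returns
#' `gamma * x`, changing the global magnitude while preserving shape.
#'
#' @inheritParams jitter_signal
#' @return Same shape as `x`.
#' @export
magnitude_scale <- function(x, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  with_seed(seed, stats::rnorm(1L, 1, sigma) * x)
}

#' Magnitude warping: modulate a signal by a smooth random curve
#'
#' Knot values `~ N(1, sigma^2)` at equally spaced positions are
#' interpolated by a natural cubic spline to a per-sample envelope `beta`;
#' the output is `x * beta`. Small random regions of the signal are thereby
#' amplified or attenuated smoothly.
#'
#' @param x Numeric vector (or matrix; the same envelope, indexed by row,
#'   multiplies every column).
#' @param sigma Knot standard deviation (>= 0; 0 is the identity).
#' @param knots Number of knots (>= 2; signal must be at least that long).
#' @param seed Optional integer seed.
#' @return Same shape as `x`.
#' @export
magnitude_warp <- function(x, sigma, knots = 4L, seed = NULL) {
  stopifnot(sigma >= 0, knots >= 2L)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < knots) stop("signal shorter than the number of warp knots")
  beta <- with_seed(seed, warp_envelope(n, sigma, knots))
  x * beta
}

warp_envelope <- function(n, sigma, knots) {
  pos <- seq(1, n, length.out = knots)
  vals <- stats::rnorm(knots, 1, sigma)
  stats::spline(pos, vals, xout = seq_len(n), method = "natural")$y
}

# apply one operator to every raw channel block of an epoch; jitter is
# independent per axis, scaling and warping share their draw/envelope
# across the 3 axes of a sensor so the sensor's direction is preserved
augment_epoch <- function(epoch, op, cfg, seed) {
  blocks <- list(ctx = epoch$acc_context %||% epoch$acc,
                 gyro = epoch$gyro, mag = epoch$mag)
  out <- with_seed(seed, switch(
    op,
    jitter = lapply(blocks, function(b)
      b + stats::rnorm(length(b), 0, cfg$jitter_sigma)),
    scale = lapply(blocks, function(b)
      stats::rnorm(1L, 1, cfg$scale_sigma) * b),
    warp = lapply(blocks, function(b)
      b * warp_envelope(nrow(b), cfg$warp_sigma, cfg$warp_knots)),
    stop("unknown operator: ", op)))
  epoch$acc_context <- out$ctx
  cs <- epoch$context_start %||% 1L
  epoch$acc <- out$ctx[cs:(cs + nrow(epoch$acc) - 1L), , drop = FALSE]
  epoch$gyro <- out$gyro
  epoch$mag <- out$mag
  epoch
}

#' Grow minority classes by seeded augmentation
#'
#' Applies the three operators (cycling jitter, scale, warp) to randomly
#' chosen source epochs of each under-represented class until every class
#' present reaches at least `target_ratio` times the majority-class count.
#' Operators act on the raw time-domain channels, so features and spectra
#' of augmented epochs are recomputed downstream. Originals are always
#' retained and augmented epochs are flagged. Intended for training folds
#' only.
#'
#' @param labeled A `labeled_epochs` object (training portion).
#' @param cfg An [augmentation_config()].
#' @param target_ratio Minimum class size as a fraction of the majority
#'   class.
#' @return A `labeled_epochs` object with an `attr(, "manifest")`
#'   data.frame recording source epoch, operator and seed per addition.
#' @export
balance_classes <- function(labeled, cfg = augmentation_config(),
                            target_ratio = 0.25) {
  counts <- table(droplevels(labeled$class))
  if (length(counts) == 0L || any(counts == 0L)) {
    counts <- counts[counts > 0L]
    warning("empty class(es) skipped during balancing")
  }
  target <- ceiling(target_ratio * max(counts))
  ops <- c("jitter", "scale", "warp")
  new_eps <- list(); new_cls <- character(); manifest <- list()
  k <- 0L
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit <= 0L) next
    idx <- which(labeled$class == cl)
    src <- with_seed(cfg$seed + 7L * match(cl, names(counts)),
                     sample(idx, deficit, replace = TRUE))
    for (j in seq_len(deficit)) {
      k <- k + 1L
      op <- ops[(k - 1L) %% 3L + 1L]
      sd_j <- cfg$seed + 1000L + k
      new_eps[[k]] <- augment_epoch(labeled$epochs[[src[j]]], op, cfg, sd_j)
      new_cls[k] <- cl
      manifest[[k]] <- data.frame(source = src[j], class = cl,
                                  operator = op, seed = sd_j)
    }
  }
  out <- labeled_epochs(c(labeled$epochs, new_eps),
                        c(as.character(labeled$class), new_cls),
                        augmented = c(labeled$augmented,
                                      rep(TRUE, length(new_eps))),
                        dropped = labeled$dropped)
  attr(out, "manifest") <- if (k) do.call(rbind, manifest) else
    data.frame(source = integer(), class = character(),
               operator = character(), seed = integer())
  out
}
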