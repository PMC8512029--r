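test_that("the feature catalog is pinned at 187 unique names", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 187L)
  expect_false(anyDuplicated(cat$name) > 0)
  expect_equal(sum(cat$domain == "time"), 114L)
  expect_equal(sum(cat$domain == "frequency"), 73L)
})

test_that("the static/dynamic split matches a brute-force running mean", {
  # constant gravity: static is the constant, dynamic vanishes
  const <- matrix(c(0, 0, 1), 150, 3, byrow = TRUE)
  sp <- static_dynamic_split(const)
  expect_equal(sp$static, const)
  expect_equal(max(abs(sp$dynamic)), 0)

  set.seed(7)
  x <- matrix(rnorm(150 * 3), 150, 3)
  sp <- static_dynamic_split(x, hz = 50L, window_s = 3)
  expect_equal(sp$static + sp$dynamic, x)
  # independent windowed-mean oracle
  oracle <- x * 0
  for (i in 1:150) {
    lo <- max(1, i - 75); hi <- min(150, i + 74)
    oracle[i, ] <- colMeans(x[lo:hi, , drop = FALSE])
  }
  expect_equal(sp$static, oracle, tolerance = 1e-12)

  # a 1 Hz tone is attenuated exactly as the moving-average oracle says
  t <- (0:149) / 50
  tone <- cbind(sin(2 * pi * t), 0, 1)
  sp <- static_dynamic_split(tone)
  om <- tone * 0
  for (i in 1:150) {
    lo <- max(1, i - 75); hi <- min(150, i + 74)
    om[i, ] <- colMeans(tone[lo:hi, , drop = FALSE])
  }
  expect_equal(sp$dynamic, tone - om, tolerance = 1e-12)
})

test_that("ODBA is the sum of absolute dynamic axis values", {
  expect_equal(odba(matrix(0, 50, 3)), rep(0, 50))
  expect_equal(odba(matrix(c(0.1, -0.2, 0.3), 1)), 0.6)
  set.seed(8)
  d <- matrix(rnorm(150), 50, 3)
  expect_equal(odba(d), abs(d[, 1]) + abs(d[, 2]) + abs(d[, 3]))
})

test_that("time-domain statistics match hand computation and degenerate rules", {
  s <- time_domain_stats(c(1, 2, 3, 4, 5))
  expect_equal(s[["mean"]], 3)
  expect_equal(s[["median"]], 3)
  expect_equal(s[["iqr"]], 2)   # type-7 quartiles: 2 and 4
  expect_equal(s[["sd"]], sqrt(2.5))
  expect_equal(s[["mad"]], 1)
  expect_equal(s[["skewness"]], 0)

  const <- time_domain_stats(rep(2.5, 10))
  expect_equal(const[["sd"]], 0)
  expect_equal(unname(const[c("skewness", "kurtosis", "invcov")]),
               c(0, 0, 0))
  expect_equal(unname(const[c("min", "max", "median", "mad", "iqr")]),
               c(2.5, 2.5, 2.5, 0, 0))

  # moment-formula oracle on a random draw
  set.seed(9)
  x <- rnorm(50)
  s <- time_domain_stats(x)
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_equal(s[["skewness"]], mean((x - m)^3) / m2^1.5, tolerance = 1e-12)
  expect_equal(s[["kurtosis"]], mean((x - m)^4) / m2^2, tolerance = 1e-12)
  expect_equal(s[["invcov"]], m / sd(x), tolerance = 1e-12)

  sym <- c(-2, -1, 0, 1, 2)
  expect_lt(abs(time_domain_stats(sym)[["skewness"]]), 1e-12)
  expect_error(time_domain_stats(1), "insufficient")
})

test_that("SMA and q behave as norms should", {
  expect_equal(signal_magnitude_area(matrix(c(0, 0, 1), 50, 3, byrow = TRUE)), 1)
  expect_equal(signal_magnitude_area(matrix(0, 50, 3)), 0)
  set.seed(10)
  a <- matrix(rnorm(150), 50, 3)
  expect_equal(signal_magnitude_area(a), mean(rowSums(abs(a))))

  expect_equal(q_norm(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(q_norm(matrix(0, 5, 3)), rep(0, 5))
  # rotation invariance of q
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(q_norm(a %*% rot), q_norm(a), tolerance = 1e-12)
})

test_that("circular variances span [0, 1] with the documented limits", {
  const <- matrix(c(1, 2, 3), 50, 3, byrow = TRUE)
  expect_equal(unname(circular_variances(const)), c(0, 0), tolerance = 1e-12)

  # 50 azimuths equally spaced on the circle: resultant cancels
  ang <- 2 * pi * (0:49) / 50
  ring <- cbind(cos(ang), sin(ang), 0)
  cv <- circular_variances(ring)
  expect_equal(cv[["cv_azimuth"]], 1, tolerance = 1e-9)

  set.seed(11)
  m <- matrix(rnorm(150), 50, 3)
  cv <- circular_variances(m)
  q <- sqrt(rowSums(m^2))
  incl <- acos(m[, 3] / q); az <- atan2(m[, 2], m[, 1])
  expect_equal(cv[["cv_inclination"]],
               1 - sqrt(mean(cos(incl))^2 + mean(sin(incl))^2),
               tolerance = 1e-12)
  expect_equal(cv[["cv_azimuth"]],
               1 - sqrt(mean(cos(az))^2 + mean(sin(az))^2),
               tolerance = 1e-12)
  expect_true(all(cv >= 0 & cv <= 1))

  zero <- circular_variances(matrix(0, 10, 3))
  expect_equal(as.numeric(zero), c(0, 0))
  expect_true(attr(zero, "degenerate"))
})

test_that("axis correlations are Pearson with a zero-variance sentinel", {
  set.seed(12)
  x <- rnorm(50)
  same <- cbind(x, x, rnorm(50))
  expect_equal(acc_pairwise_correlations(same)[["r_xy"]], 1)
  a <- matrix(rnorm(150), 50, 3)
  r <- acc_pairwise_correlations(a)
  expect_equal(r[["r_xz"]], cor(a[, 1], a[, 3]), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1))
  flat <- cbind(rep(1, 50), rnorm(50), rnorm(50))
  rf <- acc_pairwise_correlations(flat)
  expect_equal(unname(rf[c("r_xy", "r_xz")]), c(0, 0))
})

test_that("vertical velocity follows the hydrostatic conversion", {
  expect_equal(vertical_velocity(1013, 1013), 0)
  # +100.55 mbar over one second is very nearly one metre of descent
  expect_equal(vertical_velocity(1013, 1113.55), 1, tolerance = 1e-3)
  expect_equal(vertical_velocity(1113.55, 1013),
               -vertical_velocity(1013, 1113.55))
  expect_equal(vertical_velocity(1013, NA), 0)
})

test_that("spectral statistics satisfy the pinned FFT normalization (Parseval)", {
  expect_equal(unname(frequency_domain_stats(rep(0, 50))), rep(0, 8))

  set.seed(13)
  x <- rnorm(50)
  s <- frequency_domain_stats(x, nfft = 512L)
  X <- abs(fft(c(x, rep(0, 462))))
  # one-sided energy relates to the two-sided Parseval sum:
  # 2*E - |DC|^2 + |Nyquist|^2 = nfft * sum(x^2)
  expect_equal(2 * s[["energy"]] - X[1]^2 + X[257]^2, 512 * sum(x^2),
               tolerance = 1e-9)
  expect_equal(s[["power"]], s[["energy"]] / 50)
  expect_equal(s[["mean"]], mean(X[2:256]), tolerance = 1e-12)
  expect_equal(s[["max"]], max(X[2:256]), tolerance = 1e-12)
  p <- X[1:256] / sum(X[1:256])
  expect_equal(s[["entropy"]], -sum(p * log(p)), tolerance = 1e-12)

  # a single tone concentrates the spectrum: its magnitude entropy sits
  # well below both the flat-spectrum maximum log(256) and a white-noise
  # epoch (the rectangular 1-s window bounds how concentrated it can get)
  tone <- sin(2 * pi * 10 * (0:49) / 50)
  st <- frequency_domain_stats(tone)
  expect_lt(st[["entropy"]], 0.9 * log(256))
  expect_gt(st[["max"]], 10 * st[["median"]])
  noise <- frequency_domain_stats(rnorm(50))
  expect_lt(st[["entropy"]], noise[["entropy"]])
})

test_that("the extractor returns 187 finite values consistent with direct recomputation", {
  ep <- make_epoch(seed = 14)
  fv <- extract_features(ep)
  expect_length(fv, 187L)
  expect_identical(names(fv), feature_catalog()$name)
  expect_true(all(is.finite(fv)))

  # all-zero epoch: degenerate substitution rules keep everything finite
  zero <- make_epoch(acc = matrix(0, 50, 3), gyro = matrix(0, 50, 3),
                     mag = matrix(0, 50, 3))
  expect_true(all(is.finite(extract_features(zero))))

  # compositional oracle: ODBA slots equal stats of the recomputed series
  dyn <- static_dynamic_split(ep$acc_context, hz = 50L)$dynamic
  od <- odba(dyn[ep$context_start:(ep$context_start + 49), ])
  expect_equal(unname(fv[paste0("odba_", c("mean", "sd", "median", "iqr"))]),
               unname(time_domain_stats(od)[c("mean", "sd", "median", "iqr")]))
  expect_equal(fv[["odba_spec_energy"]],
               frequency_domain_stats(od)[["energy"]])
  # and a gyro axis' spectral slots equal the direct computation
  expect_equal(unname(fv[paste0("gyro_y_spec_",
                                c("power", "entropy", "energy"))]),
               unname(frequency_domain_stats(ep$gyro[, 2])[c("power",
                                                             "entropy",
                                                             "energy")]))
  expect_equal(fv[["mag_q_mean"]], mean(q_norm(ep$mag)))
})

test_that("features do not depend on the epoch's absolute position in time", {
  ep <- make_epoch(seed = 15)
  shifted <- ep
  shifted$index <- 400L
  shifted$t0 <- 399
  expect_identical(extract_features(ep), extract_features(shifted))
})

test_that("feature matrices stack one catalog-ordered row per epoch", {
  lab <- make_toy_labeled(n_per_class = 3L, seed = 16)
  fm <- extract_feature_matrix(lab)
  expect_equal(dim(fm), c(9L, 187L))
  expect_identical(colnames(fm), feature_catalog()$name)
  expect_equal(fm[4, ], extract_features(lab$epochs[[4]]))
})
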