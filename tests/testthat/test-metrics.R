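# independent transcriptions of the evaluation formulas, written as plain
# loops over the one-vs-rest tables so they share no code with the package
oracle_counts <- function(cm, i) {
  tp <- cm[i, i]
  fn <- 0; fp <- 0
  for (j in seq_len(ncol(cm))) if (j != i) { fn <- fn + cm[i, j]; fp <- fp + cm[j, i] }
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}
oracle_rates <- function(cm, i) {
  b <- oracle_counts(cm, i)
  c(if (b$tp + b$fn > 0) b$tp / (b$tp + b$fn) else 0,
    if (b$tn + b$fp > 0) b$tn / (b$tn + b$fp) else 0,
    if (b$tp + b$fp > 0) b$tp / (b$tp + b$fp) else 0,
    if (2 * b$tp + b$fn + b$fp > 0) 2 * b$tp / (2 * b$tp + b$fn + b$fp) else 0)
}
oracle_mcc <- function(cm, i) {
  b <- oracle_counts(cm, i)
  den <- (b$tp + b$fp) * (b$tp + b$fn) * (b$tn + b$fp) * (b$tn + b$fn)
  if (den == 0) return(0)
  (b$tp * b$tn - b$fp * b$fn) / sqrt(den)
}
oracle_kappa <- function(cm, i) {
  b <- oracle_counts(cm, i)
  n <- b$tp + b$fn + b$fp + b$tn
  po <- (b$tp + b$tn) / n
  pe <- ((b$tp + b$fp) * (b$tp + b$fn) + (b$tn + b$fn) * (b$tn + b$fp)) / n^2
  if (pe >= 1) 0 else (po - pe) / (1 - pe)
}
oracle_overall_kappa <- function(cm) {
  tps <- fns <- fps <- tns <- 0; accs <- numeric(nrow(cm))
  for (i in seq_len(nrow(cm))) {
    b <- oracle_counts(cm, i)
    tps <- tps + b$tp; fns <- fns + b$fn; fps <- fps + b$fp; tns <- tns + b$tn
    accs[i] <- (b$tp + b$tn) / (b$tp + b$tn + b$fp + b$fn)
  }
  pex <- ((tps + fns) * (tps + fps) + (fps + tns) * (fns + tns)) /
    (tps + tns + fps + fns)^2
  pox <- mean(accs)
  max((pox - pex) / (1 - pex), (pex - pox) / (1 - pex))
}

test_that("confusion matrices have truth rows and prediction columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         classes = c("a", "b"))
  expect_equal(unname(cm["a", "b"]), 1L)
  expect_equal(sum(cm), 3)
})

test_that("per-class rates evaluate the worked binary example", {
  cm <- matrix(c(30, 10, 5, 55), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  class(cm) <- c("confusion_matrix", class(cm))
  r <- per_class_rates(cm, "pos")
  expect_equal(r[["sensitivity"]], 0.75)
  expect_equal(r[["specificity"]], 11 / 12)
  expect_equal(r[["precision"]], 6 / 7)
  expect_equal(r[["f1"]], 0.8)
  # Po = 0.85; Pe = (35*40 + 65*60) / 100^2 = 0.53
  expect_equal(per_class_kappa(cm, "pos"), (0.85 - 0.53) / (1 - 0.53))
  expect_equal(per_class_kappa(cm, "pos"), 0.680851064, tolerance = 1e-8)
})

test_that("perfect and inverted classifiers hit the metric extremes", {
  perf <- confusion_matrix(rep(letters[1:9], 10), rep(letters[1:9], 10),
                           classes = letters[1:9])
  for (cl in letters[1:9]) {
    expect_equal(unname(per_class_rates(perf, cl)), rep(1, 4))
    expect_equal(per_class_mcc(perf, cl), 1)
    expect_equal(per_class_kappa(perf, cl), 1)
  }
  expect_equal(overall_kappa(perf), 1)
  rep_perf <- metric_report(perf)
  expect_equal(unname(rep_perf$overall), rep(1, 5))

  inv <- confusion_matrix(rep(c("a", "b"), c(10, 10)),
                          rep(c("b", "a"), c(10, 10)), classes = c("a", "b"))
  expect_equal(per_class_mcc(inv, "a"), -1)

  # class never true and never predicted: flagged zeros
  cm0 <- confusion_matrix(rep("a", 5), rep("a", 5), classes = c("a", "b"))
  rb <- per_class_rates(cm0, "b")
  expect_equal(rb[["sensitivity"]], 0)
  expect_equal(rb[["precision"]], 0)
  expect_true("sensitivity" %in% attr(rb, "flagged"))
})

test_that("all metric implementations match the independent transcriptions", {
  set.seed(41)
  for (rep_i in 1:100) {
    cm <- matrix(rpois(81, sample(c(2, 8, 30), 1)), 9, 9,
                 dimnames = list(letters[1:9], letters[1:9]))
    class(cm) <- c("confusion_matrix", class(cm))
    for (i in 1:9) {
      expect_equal(unname(per_class_rates(cm, i)), oracle_rates(cm, i),
                   tolerance = 1e-9)
      expect_equal(per_class_mcc(cm, i), oracle_mcc(cm, i),
                   tolerance = 1e-9)
      expect_equal(as.numeric(per_class_kappa(cm, i)), oracle_kappa(cm, i),
                   tolerance = 1e-9)
    }
    expect_equal(as.numeric(overall_kappa(cm)), oracle_overall_kappa(cm),
                 tolerance = 1e-9)
  }
})

test_that("chance-level predictions score near-zero kappa", {
  set.seed(42)
  n <- 1e5
  truth <- sample(letters[1:9], n, replace = TRUE)
  pred <- sample(letters[1:9], n, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes = letters[1:9])
  for (i in c(1, 5, 9))
    expect_lt(abs(per_class_kappa(cm, i)), 0.02)
  expect_lt(abs(overall_kappa(cm)), 0.02)
})

test_that("overall means are macro averages, distinct from micro averages", {
  cm <- confusion_matrix(rep(c("a", "b"), c(10, 10)),
                         c(rep("a", 4), rep("b", 6), rep("b", 8), rep("a", 2)),
                         classes = c("a", "b"))
  r <- metric_report(cm)
  expect_equal(r$overall[["sensitivity"]], (0.4 + 0.8) / 2)

  # imbalanced counterexample: macro and micro sensitivity differ
  cm2 <- confusion_matrix(rep(c("a", "b"), c(90, 10)),
                          c(rep("a", 90), rep("a", 9), "b"),
                          classes = c("a", "b"))
  macro <- metric_report(cm2)$overall[["sensitivity"]]
  micro <- sum(diag(cm2)) / sum(cm2)
  expect_false(isTRUE(all.equal(macro, micro)))

  # F1 is the harmonic mean of precision and sensitivity
  set.seed(43)
  cm3 <- matrix(rpois(81, 6), 9, 9, dimnames = list(letters[1:9], letters[1:9]))
  class(cm3) <- c("confusion_matrix", class(cm3))
  for (i in 1:9) {
    r3 <- per_class_rates(cm3, i)
    h <- 2 / (1 / r3[["precision"]] + 1 / r3[["sensitivity"]])
    expect_equal(r3[["f1"]], h, tolerance = 1e-12)
  }
})

test_that("class order permutations move per-class metrics but not overall ones", {
  set.seed(44)
  truth <- sample(letters[1:5], 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.7, truth, sample(letters[1:5], 500, TRUE))
  cm1 <- confusion_matrix(truth, pred, classes = letters[1:5])
  perm <- c("c", "a", "e", "b", "d")
  cm2 <- confusion_matrix(truth, pred, classes = perm)
  r1 <- metric_report(cm1); r2 <- metric_report(cm2)
  expect_equal(r1$overall, r2$overall, tolerance = 1e-12)
  expect_equal(r1$per_class[r1$per_class$class == "c", -1],
               r2$per_class[r2$per_class$class == "c", -1],
               ignore_attr = TRUE)
})

test_that("binary one-vs-rest kappa and MCC share their sign", {
  set.seed(45)
  for (i in 1:50) {
    cm <- matrix(rpois(4, 10) + 1, 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    class(cm) <- c("confusion_matrix", class(cm))
    k <- as.numeric(per_class_kappa(cm, 1))
    m <- per_class_mcc(cm, 1)
    expect_equal(sign(round(k, 12)), sign(round(m, 12)))
  }
})

test_that("kappa bands label agreement as reported", {
  expect_equal(interpret_kappa(0.833), "almost-perfect")
  expect_equal(interpret_kappa(0.45), "moderate")
  expect_equal(interpret_kappa(1.0), "almost-perfect")
  expect_equal(interpret_kappa(0.75), "substantial")
  expect_equal(interpret_kappa(0.605), "moderate")  # gap goes to the lower band
  expect_equal(interpret_kappa(0.1), "below-moderate")
  expect_error(interpret_kappa(1.2))
})
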