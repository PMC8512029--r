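#' Multiclass confusion matrix
#'
#' Rows are truth, columns are prediction, in a fixed class order shared by
#' all models of an experiment.
#'
#' @param truth Factor or character vector of true classes.
#' @param pred Factor or character vector of predicted classes.
#' @param classes Class order; defaults to the union of levels.
#' @return A square integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(pred)))
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(truth = classes, prediction = classes)
  structure(m, class = c("confusion_matrix", class(m)))
}

# one-vs-rest binary counts for one class of a multiclass matrix
binary_counts <- function(cm, class) {
  i <- if (is.character(class)) match(class, rownames(cm)) else class
  if (is.na(i) || i < 1L || i > nrow(cm)) stop("class not in matrix: ", class)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-class sensitivity, specificity, precision and F1
#'
#' One-vs-rest rates for one class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 `2TP/(2TP+FN+FP)`. A zero
#' denominator yields 0 (attribute `flagged` lists which rates were
#' degenerate).
#'
#' @param cm A [confusion_matrix()].
#' @param class Class name or index.
#' @return Named numeric vector of the four rates, each in `[0, 1]`.
#' @export
per_class_rates <- function(cm, class) {
  b <- binary_counts(cm, class)
  safe <- function(num, den) if (den > 0) num / den else 0
  out <- c(sensitivity = safe(b["tp"], b["tp"] + b["fn"]),
           specificity = safe(b["tn"], b["tn"] + b["fp"]),
           precision = safe(b["tp"], b["tp"] + b["fp"]),
           f1 = safe(2 * b["tp"], 2 * b["tp"] + b["fn"] + b["fp"]))
  names(out) <- c("sensitivity", "specificity", "precision", "f1")
  flg <- c(b["tp"] + b["fn"], b["tn"] + b["fp"], b["tp"] + b["fp"],
           2 * b["tp"] + b["fn"] + b["fp"]) == 0
  if (any(flg)) attr(out, "flagged") <- names(out)[flg]
  out
}

#' Per-class Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` on the
#' one-vs-rest table; 0 when the denominator vanishes.
#'
#' @inheritParams per_class_rates
#' @return Scalar in `[-1, 1]`.
#' @export
per_class_mcc <- function(cm, class) {
  b <- as.numeric(binary_counts(cm, class))  # double: products can overflow int
  den <- sqrt((b[1] + b[3]) * (b[1] + b[2]) * (b[4] + b[3]) * (b[4] + b[2]))
  if (den == 0) return(0)
  (b[1] * b[4] - b[3] * b[2]) / den
}

#' Per-class (one-vs-rest) Cohen's kappa
#'
#' Binary kappa `(Po - Pe) / (1 - Pe)` with observed agreement
#' `Po = (TP+TN)/N` and chance agreement
#' `Pe = ((TP+FP)(TP+FN) + (TN+FN)(TN+FP)) / N^2`; 0 (flagged) when
#' `Pe = 1`.
#'
#' @inheritParams per_class_rates
#' @return Scalar kappa (<= 1).
#' @export
per_class_kappa <- function(cm, class) {
  b <- as.numeric(binary_counts(cm, class))
  n <- sum(b)
  po <- (b[1] + b[4]) / n
  pe <- ((b[1] + b[3]) * (b[1] + b[2]) + (b[4] + b[2]) * (b[4] + b[3])) / n^2
  if (1 - pe <= 0) {
    out <- 0
    attr(out, "flagged") <- "pe_one"
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Overall kappa from class-summed one-vs-rest counts
#'
#' The study's overall-kappa procedure: sum TP, FP, FN, TN (and the actual
#' positive and negative counts P and N) over all classes, form the
#' expected agreement
#' `Pex = (P*(TPs+FPs) + N*(FNs+TNs)) / (TPs+TNs+FPs+FNs)^2`,
#' take the observed term `Pox` as the mean one-vs-rest accuracy across
#' classes, and report the larger of `(Pox-Pex)/(1-Pex)` and
#' `(Pex-Pox)/(1-Pex)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar overall kappa.
#' @export
overall_kappa <- function(cm) {
  bs <- vapply(seq_len(nrow(cm)), function(i) binary_counts(cm, i),
               numeric(4))
  tps <- sum(bs["tp", ]); fns <- sum(bs["fn", ])
  fps <- sum(bs["fp", ]); tns <- sum(bs["tn", ])
  px <- tps + fns          # actual positives, summed over classes
  nx <- fps + tns          # actual negatives, summed over classes
  tot <- tps + tns + fps + fns
  pex <- (px * (tps + fps) + nx * (fns + tns)) / tot^2
  pox <- mean((bs["tp", ] + bs["tn", ]) / colSums(bs))
  if (1 - pex <= 0) {
    out <- 0
    attr(out, "flagged") <- "pe_one"
    return(out)
  }
  max((pox - pex) / (1 - pex), (pex - pox) / (1 - pex))
}

#' Qualitative agreement label for a kappa value
#'
#' Bands: below 0.4 below-moderate, `[0.4, 0.61)` moderate, `[0.61, 0.81)`
#' substantial, `[0.81, 1]` almost perfect.
#'
#' @param kappa Numeric kappa (<= 1).
#' @return Character label.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(kappa <= 1 + 1e-12)
  if (kappa < 0.4) "below-moderate"
  else if (kappa < 0.61) "moderate"
  else if (kappa < 0.81) "substantial"
  else "almost-perfect"
}

#' Full metric report for a confusion matrix
#'
#' Per-class sensitivity, specificity, precision, F1, MCC and one-vs-rest
#' kappa, plus overall values: unweighted (macro) means across classes for
#' every metric except kappa, whose overall value follows the class-summed
#' procedure of [overall_kappa()].
#'
#' @param cm A [confusion_matrix()].
#' @return A `metric_report`: list with `per_class` (data.frame), `overall`
#'   (named vector), `kappa_label` and the matrix itself.
#' @export
metric_report <- function(cm) {
  classes <- rownames(cm)
  per <- t(vapply(classes, function(cl) {
    r <- per_class_rates(cm, cl)
    c(r, mcc = per_class_mcc(cm, cl), kappa = as.numeric(per_class_kappa(cm, cl)))
  }, numeric(6)))
  per <- data.frame(class = classes, per, row.names = NULL)
  ov <- c(colMeans(per[, c("sensitivity", "specificity", "f1", "mcc")]),
          kappa = as.numeric(overall_kappa(cm)))
  structure(list(per_class = per, overall = ov,
                 kappa_label = interpret_kappa(ov[["kappa"]]),
                 confusion = cm),
            class = "metric_report")
}

#' Macro-averaged overall metrics of a report
#'
#' @param report A `metric_report`.
#' @return Named vector of the overall metrics.
#' @export
overall_means <- function(report) report$overall

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("Metric report over", nrow(x$per_class), "classes\n")
  print(cbind(class = x$per_class$class,
              round(x$per_class[, -1], digits)), row.names = FALSE)
  cat("overall:",
      paste(sprintf("%s=%.*f", names(x$overall), digits, x$overall),
            collapse = "  "), "\n")
  cat("kappa agreement:", x$kappa_label, "\n")
  invisible(x)
}
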