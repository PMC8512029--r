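#' Random forest configuration
#'
#' 200 un-pruned trees on with-replacement bootstrap samples of the
#' training data (each bootstrap is expected to contain ~62.3 percent of
#' the unique observations), with `m` predictors sampled at each split.
#'
#' @param n_trees Number of trees.
#' @param m Predictors tried per split; default `floor(sqrt(p))`.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 200L, m = NULL) {
  list(n_trees = as.integer(n_trees), m = m)
}

#' Support vector machine configuration
#'
#' Gaussian radial-basis kernel, one-vs-one multiclass reduction, features
#' standardized with training-set statistics.
#'
#' @param cost Soft-margin cost C.
#' @param gamma Kernel width; default `1 / p` on standardized features.
#' @return An `svm_config` list.
#' @export
svm_config <- function(cost = 1, gamma = NULL) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  list(cost = cost, gamma = gamma)
}

#' CNN training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction of training data held out per class for early
#'   stopping (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(epochs = 30L, batch_size = 64L, lr = 1e-3,
                       val_frac = 0, patience = 10L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, val_frac = val_frac, patience = as.integer(patience))
}

#' Fit a behavior classifier
#'
#' One front-end for the three classifiers compared in the pipeline. `rf`
#' and `svm` consume the 187-column handcrafted feature matrix; `cnn`
#' consumes the `256 x 9 x n` spectral array. Each model owns its input
#' preprocessing, fitted on the training data only: the SVM standardizes
#' features, the CNN z-scores each spectral bin. All three are
#' seed-deterministic.
#'
#' @param x Feature matrix (n x 187) for `rf`/`svm`, or spectral array
#'   (bins x channels x n) for `cnn`.
#' @param y Factor (or character) of behavior classes, length n; at least
#'   two classes must be present.
#' @param method One of "rf", "svm", "cnn".
#' @param config Optional [rf_config()], [svm_config()] or [cnn_config()].
#' @param seed Integer seed controlling bootstrap, initialization,
#'   shuffling and dropout.
#' @return A `behavior_model` object with `predict`, `print` and `summary`
#'   methods.
#' @export
fit_behavior_model <- function(x, y, method = c("rf", "svm", "cnn"),
                               config = NULL, seed = 1L) {
  method <- match.arg(method)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L)
    stop("degenerate training set: need at least 2 classes, got ",
         nlevels(y))
  fitted <- switch(method,
    rf = {
      cfg <- config %||% rf_config()
      m <- cfg$m %||% max(1L, floor(sqrt(ncol(x))))
      fit <- with_seed(seed, randomForest::randomForest(
        x = as.matrix(x), y = y, ntree = cfg$n_trees, mtry = m))
      list(fit = fit, config = cfg)
    },
    svm = {
      cfg <- config %||% svm_config()
      x <- as.matrix(x)
      ctr <- colMeans(x)
      scl <- pmax(apply(x, 2, stats::sd), 1e-8)
      xs <- scale(x, ctr, scl)
      fit <- with_seed(seed, e1071::svm(
        x = xs, y = y, kernel = "radial", cost = cfg$cost,
        gamma = cfg$gamma %||% 1 / ncol(x), scale = FALSE))
      list(fit = fit, config = cfg, center = ctr, scale = scl)
    },
    cnn = {
      cfg <- config %||% cnn_config()
      stopifnot(length(dim(x)) == 3L)
      scfg <- fit_normalizer(x, spectral_config(nfft = 2L * dim(x)[1]))
      xn <- apply_normalizer(x, scfg)
      arch <- cnn_architecture(n_bins = dim(x)[1], n_channels = dim(x)[2],
                               n_classes = nlevels(y))
      tr <- cnn_train(xn, y, arch, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, lr = cfg$lr,
                      val_frac = cfg$val_frac, patience = cfg$patience,
                      seed = seed)
      list(fit = tr$params, config = cfg, arch = arch, norm = scfg,
           trace = tr$trace)
    })
  structure(c(fitted,
              list(method = method, classes = levels(y), seed = seed,
                   n_train = length(y))),
            class = c(paste0("behavior_model_", method), "behavior_model"))
}

#' Predict behavior classes
#'
#' @param object A fitted `behavior_model`.
#' @param newdata Input in the model's representation (feature matrix for
#'   rf/svm, spectral array for cnn); the model's stored preprocessing is
#'   applied.
#' @param type `"class"` for labels, `"prob"` for per-class scores (class
#'   vote fractions for rf, softmax probabilities for cnn; not available
#'   for svm).
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix of scores.
#' @export
predict.behavior_model <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  switch(object$method,
    rf = {
      if (length(dim(newdata)) != 2L) stop("rf expects a feature matrix")
      stats::predict(object$fit, as.matrix(newdata),
                     type = if (type == "class") "response" else "vote")
    },
    svm = {
      if (type == "prob") stop("per-class scores unsupported for svm")
      if (length(dim(newdata)) != 2L) stop("svm expects a feature matrix")
      xs <- scale(as.matrix(newdata), object$center, object$scale)
      stats::predict(object$fit, xs)
    },
    cnn = {
      if (length(dim(newdata)) != 3L) stop("cnn expects a spectral array")
      xn <- apply_normalizer(newdata, object$norm)
      probs <- cnn_predict_probs(object$fit, xn, object$arch)
      colnames(probs) <- object$classes
      if (type == "prob") probs
      else factor(object$classes[max.col(probs, ties.method = "first")],
                  levels = object$classes)
    })
}

#' @export
print.behavior_model <- function(x, ...) {
  cat("behavior_model (", x$method, "), ", length(x$classes), " classes, ",
      x$n_train, " training epochs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.behavior_model <- function(object, ...) {
  print(object)
  if (object$method == "rf")
    cat("  trees:", object$fit$ntree, " mtry:", object$fit$mtry, "\n")
  if (object$method == "svm")
    cat("  support vectors:", object$fit$tot.nSV, "\n")
  if (object$method == "cnn")
    cat("  flatten size:", object$arch$flatten_size,
        " final train loss:", round(utils::tail(object$trace, 1), 4), "\n")
  invisible(object)
}

#' Random forest feature importance
#'
#' Per-feature importance as the total decrease in node impurity (Gini)
#' from splits on that feature, weighted by node size and averaged over
#' trees, ranked descending.
#'
#' @param model A fitted `behavior_model` with method `"rf"`.
#' @return Data.frame with columns `feature` and `importance`, sorted
#'   descending.
#' @export
rf_feature_importance <- function(model) {
  if (!inherits(model, "behavior_model") || model$method != "rf")
    stop("feature importance is only defined for rf models")
  imp <- model$fit$importance[, "MeanDecreaseGini"]
  out <- data.frame(feature = rownames(model$fit$importance),
                    importance = as.numeric(imp))
  out[order(-out$importance), , drop = FALSE]
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits the labeled epochs into k stratified folds; each fold trains on
#' the remaining 80 percent and tests on its 20 percent. Representation
#' building, optional minority-class augmentation, and all preprocessing
#' (feature standardization, spectral normalization) happen inside the
#' training fold only, so no information leaks into test folds (augmented
#' epochs never enter a test fold).
#'
#' @param labeled A `labeled_epochs` object (already filtered to the
#'   training classes).
#' @param method "rf", "svm" or "cnn".
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and model fitting).
#' @param config Optional model configuration.
#' @param augment Optional [augmentation_config()]; when given, training
#'   folds are balanced with [balance_classes()] before fitting.
#' @param target_ratio Balancing target passed to [balance_classes()].
#' @return List with `folds` (one [confusion_matrix()] per fold), `pooled`
#'   (their sum) and `assignments` (fold id per epoch).
#' @export
crossvalidate <- function(labeled, method = c("rf", "svm", "cnn"), k = 5L,
                          seed = 1L, config = NULL, augment = NULL,
                          target_ratio = 0.25) {
  method <- match.arg(method)
  y <- droplevels(labeled$class)
  counts <- table(y)
  if (any(counts < k))
    stop("class(es) with fewer than k epochs: ",
         paste(names(counts)[counts < k], collapse = ", "))
  fold <- integer(length(y))
  with_seed(seed, for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  })
  represent <- function(lab) {
    if (method == "cnn") build_spectral_array(lab)
    else extract_feature_matrix(lab)
  }
  cms <- lapply(seq_len(k), function(f) {
    tr <- labeled[fold != f]
    te <- labeled[fold == f]
    if (!is.null(augment))
      tr <- balance_classes(tr, augment, target_ratio = target_ratio)
    model <- fit_behavior_model(represent(tr), droplevels(tr$class),
                                method = method, config = config,
                                seed = seed + f)
    pred <- predict(model, represent(te))
    confusion_matrix(droplevels(te$class), pred, classes = levels(y))
  })
  pooled <- Reduce(`+`, lapply(cms, unclass))
  class(pooled) <- c("confusion_matrix", class(pooled))
  list(folds = cms, pooled = pooled, assignments = fold)
}
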