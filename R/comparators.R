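#' Comparator specification
#'
#' Declares a pluggable classifier evaluated under the same grouped
#' cross-validation and prediction contract as the PLS-DA model.
#'
#' @param kind `"svm_rbf"` (support vector machine, radial basis
#'   function kernel) or `"gradient_boosted_trees"`.
#' @param hyper_grid Optional named list of hyperparameter vectors to
#'   grid-search; `NULL` uses a small built-in grid.
#' @return A `comparator_spec` list.
#' @export
comparator_spec <- function(kind = c("svm_rbf", "gradient_boosted_trees"),
                            hyper_grid = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyper_grid = hyper_grid),
            class = "comparator_spec")
}

default_hyper_grid <- function(kind, p) {
  switch(kind,
    svm_rbf = list(cost = c(1, 10, 100), gamma = c(0.1, 1, 10) / p),
    gradient_boosted_trees = list(max_depth = c(2, 3), eta = 0.3,
                                  nrounds = 50))
}

comparator_backend_ok <- function(kind) {
  pkg <- switch(kind, svm_rbf = "e1071", gradient_boosted_trees = "xgboost")
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("comparator backend '", pkg, "' is not installed; the PLS-DA ",
         "model is unaffected", call. = FALSE)
  }
  invisible(TRUE)
}

fit_comparator_once <- function(kind, x, y, pars, seed = 1L) {
  if (kind == "svm_rbf") {
    e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
               cost = pars$cost, gamma = pars$gamma, scale = FALSE)
  } else {
    set.seed(seed)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = pars$max_depth, eta = pars$eta,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = pars$nrounds, verbose = 0)
  }
}

predict_comparator_once <- function(kind, fit, x) {
  if (kind == "svm_rbf") {
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
    # orient so larger means class "1"
    s <- drop(dv) * if (colnames(dv) == "0/1") -1 else 1
    stats::plogis(s)
  } else {
    predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
  }
}

#' Fit a comparator classifier with grid-searched hyperparameters
#'
#' Tunes the comparator by misclassification error under the supplied
#' fold assignment (the same grouped venetian-blinds folds the PLS-DA
#' model uses), then refits on all rows. The fitted object honors the
#' common prediction contract: scores in `[0, 1]` with the positive
#' class above 0.5.
#'
#' @param spec A [comparator_spec()].
#' @param train A `spectrum_set`.
#' @param labels Class labels; defaults to `train$meta$class`.
#' @param folds Per-row fold indices.
#' @param threshold Decision threshold on the score (default 0.5).
#' @param positive,negative Class labels coded 1 and 0.
#' @param seed Seed controlling any backend randomness.
#' @return A `comparator_model` with the tuned hyperparameters in
#'   `$hyper`.
#' @export
fit_comparator <- function(spec, train, labels = NULL, folds,
                           threshold = 0.5, positive = "C", negative = "H",
                           seed = 1L) {
  comparator_backend_ok(spec$kind)
  if (is.null(labels)) labels <- train$meta$class
  y <- as.numeric(labels == positive)
  x <- train$x
  grid <- spec$hyper_grid
  if (is.null(grid)) grid <- default_hyper_grid(spec$kind, ncol(x))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  cv_err <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pars <- as.list(combos[i, , drop = FALSE])
    pred <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      hold <- folds == f
      fit <- fit_comparator_once(spec$kind, x[!hold, , drop = FALSE],
                                 y[!hold], pars, seed)
      pred[hold] <- predict_comparator_once(spec$kind, fit,
                                            x[hold, , drop = FALSE])
    }
    cv_err[i] <- mean((pred >= threshold) != y)
  }
  best <- as.list(combos[which.min(cv_err), , drop = FALSE])
  fit <- fit_comparator_once(spec$kind, x, y, best, seed)
  structure(list(kind = spec$kind, fit = fit, hyper = best,
                 cv_error = min(cv_err), threshold = threshold,
                 wavenumbers = train$wavenumbers,
                 class_coding = c(negative = negative, positive = positive),
                 seed = seed),
            class = "comparator_model")
}

# fit a comparator with fixed hyperparameters (no tuning) -- used when
# cross-validating an already-tuned comparator
fit_comparator_fixed <- function(kind, train, labels = NULL, hyper,
                                 threshold = 0.5, positive = "C",
                                 negative = "H", seed = 1L) {
  comparator_backend_ok(kind)
  if (is.null(labels)) labels <- train$meta$class
  y <- as.numeric(labels == positive)
  fit <- fit_comparator_once(kind, train$x, y, hyper, seed)
  structure(list(kind = kind, fit = fit, hyper = hyper, cv_error = NA_real_,
                 threshold = threshold, wavenumbers = train$wavenumbers,
                 class_coding = c(negative = negative, positive = positive),
                 seed = seed),
            class = "comparator_model")
}

#' @export
predict.comparator_model <- function(object, set, ...) {
  x <- if (inherits(set, "spectrum_set")) {
    check_same_grid(object$wavenumbers, set$wavenumbers)
    set$x
  } else as.matrix(set)
  score <- predict_comparator_once(object$kind, object$fit, x)
  cls <- ifelse(score >= object$threshold,
                object$class_coding[["positive"]],
                object$class_coding[["negative"]])
  data.frame(score = score, class = cls, side = score - object$threshold)
}
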