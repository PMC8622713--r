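#' Grouped venetian-blinds fold assignment
#'
#' Samples are ordered lexicographically by id; sample j (0-based rank)
#' goes to fold `j mod k`, and every row of a sample inherits its fold,
#' so the two representative spectra of a sample always share a blind.
#'
#' @param sample_ids Per-row sample identifiers (each sample must have
#'   exactly 2 rows).
#' @param k Number of folds (default 10); must be >= 2 and at most the
#'   number of samples.
#' @return Integer vector of per-row fold indices in `0:(k-1)`.
#' @export
venetian_blinds <- function(sample_ids, k = 10) {
  tab <- table(sample_ids)
  if (any(tab != 2)) {
    stop("every sample must have exactly 2 spectra; offending: ",
         paste(names(tab)[tab != 2], collapse = ", "), call. = FALSE)
  }
  samples <- sort(unique(as.character(sample_ids)))
  if (k < 2) stop("k must be at least 2 (k = 1 leaves no held-out data)",
                  call. = FALSE)
  if (k > length(samples)) {
    stop("k (", k, ") exceeds the number of samples (", length(samples), ")",
         call. = FALSE)
  }
  fold_of <- (seq_along(samples) - 1L) %% as.integer(k)
  names(fold_of) <- samples
  unname(fold_of[as.character(sample_ids)])
}

#' Confusion matrix counts
#'
#' @param predicted,truth Class labels.
#' @param positive Positive-class label (default `"C"`).
#' @return A `confusion_matrix` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth, positive = "C") {
  p <- predicted == positive; t <- truth == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_matrix")
}

#' Sensitivity, TP / (TP + FN)
#' @param cm A `confusion_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) stop("sensitivity undefined: no positive rows",
                               call. = FALSE)
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity, TN / (TN + FP)
#' @param cm A `confusion_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) stop("specificity undefined: no negative rows",
                               call. = FALSE)
  cm$tn / (cm$tn + cm$fp)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all unique scores as thresholds (ties step simultaneously) and
#' integrates by the trapezoid rule.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Class labels; both classes must be present.
#' @param positive Positive-class label (default `"C"`).
#' @return A `roc_curve` list with `points` (data frame `fpr`, `tpr`,
#'   `threshold`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "C") {
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present",
                                     call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  keep <- c(diff(s) != 0, TRUE)                # last index of each tie group
  tpr <- c(0, cumsum(yy)[keep] / n_pos)
  fpr <- c(0, cumsum(!yy)[keep] / n_neg)
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc),
            class = "roc_curve")
}

#' Grouped cross-validation of a classifier
#'
#' For each fold: fit on the complement, predict the held-out rows; the
#' pooled held-out scores give the headline confusion matrix,
#' sensitivity, specificity, ROC and AUC. Calibration (resubstitution)
#' metrics from a fit on all rows are reported alongside. The grouping
#' invariant (no sample split across folds) is asserted on every run.
#'
#' @param model_factory `function(train_set, train_labels)` returning a
#'   fitted model whose `predict(model, set)` yields a data frame with
#'   `score` and `class`.
#' @param set A `spectrum_set`.
#' @param labels Class labels; defaults to `set$meta$class`.
#' @param folds Per-row fold indices (e.g. [venetian_blinds()]).
#' @param positive Positive-class label (default `"C"`).
#' @return A `cv_report`: `folds`, `scores`, `predicted`, `confusion`,
#'   `sensitivity`, `specificity`, `roc`, `auc`, `per_fold` (data
#'   frame), and `calibration` (list with the same metric set).
#' @export
cross_validate <- function(model_factory, set, labels = NULL, folds,
                           positive = "C") {
  if (is.null(labels)) labels <- set$meta$class
  n <- n_spectra(set)
  stopifnot(length(folds) == n, length(labels) == n)
  split_samples <- tapply(folds, set$meta$sample_id,
                          function(f) length(unique(f)))
  if (any(split_samples > 1)) {
    stop("grouping violated: sample(s) split across folds: ",
         paste(names(split_samples)[split_samples > 1], collapse = ", "),
         call. = FALSE)
  }
  scores <- rep(NA_real_, n)
  predicted <- rep(NA_character_, n)
  per_fold <- list()
  for (f in sort(unique(folds))) {
    hold <- folds == f
    model <- model_factory(subset_rows(set, !hold), labels[!hold])
    pr <- predict(model, subset_rows(set, hold))
    scores[hold] <- pr$score
    predicted[hold] <- pr$class
    per_fold[[as.character(f)]] <- data.frame(
      fold = f, n = sum(hold),
      error = mean(pr$class != labels[hold]))
  }
  if (anyNA(scores)) stop("folds do not partition the rows", call. = FALSE)
  cm <- confusion_matrix(predicted, labels, positive)
  roc <- roc_auc(scores, labels, positive)
  cal_model <- model_factory(set, labels)
  cal_pr <- predict(cal_model, set)
  cal_cm <- confusion_matrix(cal_pr$class, labels, positive)
  structure(list(folds = folds, scores = scores, predicted = predicted,
                 labels = labels, confusion = cm,
                 sensitivity = sensitivity(cm), specificity = specificity(cm),
                 roc = roc, auc = roc$auc,
                 per_fold = do.call(rbind, per_fold),
                 calibration = list(
                   scores = cal_pr$score, confusion = cal_cm,
                   sensitivity = sensitivity(cal_cm),
                   specificity = specificity(cal_cm),
                   auc = roc_auc(cal_pr$score, labels, positive)$auc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cm <- x$confusion
  cat("<cv_report> pooled held-out metrics\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm$tp, cm$fp, cm$tn, cm$fn))
  cat(sprintf("  sensitivity=%.3f specificity=%.3f AUC=%.4f\n",
              x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
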