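#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares discriminant analysis for two classes, coded
#' H -> 0 and C -> 1, fitted by the NIPALS PLS1 recursion on
#' mean-centered X and y with X-block deflation. The decomposition is
#' X = t p' + E, y = u q' + f; the regression vector is assembled from
#' the weights, loadings and y-loadings so that
#' `yhat = (x - x_mean) b + y_mean`.
#'
#' @param train A `spectrum_set` of training spectra.
#' @param labels Class labels (`"H"`/`"C"`); defaults to
#'   `train$meta$class`.
#' @param n_lv Number of latent variables (<= min(rows - 1, cols)).
#' @param threshold Decision cutoff on the predicted score (default 0.5).
#' @param positive,negative Class labels coded 1 and 0.
#' @return A `plsda_model` with elements `weights` (W), `x_loadings` (P),
#'   `y_loadings` (q), `x_scores` (T), `y_scores` (U), `coef_by_lv`
#'   (regression vectors for 1..n_lv components), `b`, `x_mean`,
#'   `y_mean`, `explained_x_variance` (% per LV), `threshold`,
#'   `wavenumbers`, `class_coding`, `mode`.
#' @export
fit_plsda <- function(train, labels = NULL, n_lv = 2, threshold = 0.5,
                      positive = "C", negative = "H") {
  x <- train$x
  if (is.null(labels)) labels <- train$meta$class
  if (!all(labels %in% c(positive, negative))) {
    stop("labels must be ", negative, " or ", positive, call. = FALSE)
  }
  y <- as.numeric(labels == positive)
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  if (n_lv > min(n - 1, p)) {
    stop("n_lv (", n_lv, ") exceeds min(rows - 1, cols) = ", min(n - 1, p),
         call. = FALSE)
  }
  x_mean <- colMeans(x); y_mean <- mean(y)
  Xc <- sweep(x, 2, x_mean); yc <- y - y_mean
  tot_ss <- sum(Xc^2)
  W <- P <- matrix(0, p, n_lv)
  Tm <- U <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  expl <- numeric(n_lv)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { n_lv <- a - 1L; break }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    u_a <- if (abs(q_a) > 1e-14) yd / q_a else yd
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    Tm[, a] <- t_a; U[, a] <- u_a
    expl[a] <- 100 * tt * sum(p_a^2) / tot_ss
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
  }
  if (n_lv < 1) stop("no predictive latent variable found", call. = FALSE)
  W <- W[, seq_len(n_lv), drop = FALSE]; P <- P[, seq_len(n_lv), drop = FALSE]
  Tm <- Tm[, seq_len(n_lv), drop = FALSE]; U <- U[, seq_len(n_lv), drop = FALSE]
  q <- q[seq_len(n_lv)]; expl <- expl[seq_len(n_lv)]
  R <- W %*% solve(crossprod(P, W))            # X-rotations
  coef_by_lv <- sapply(seq_len(n_lv), function(a)
    R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  coef_by_lv <- matrix(coef_by_lv, nrow = p)
  structure(list(n_lv = n_lv, weights = W, x_loadings = P, y_loadings = q,
                 x_scores = Tm, y_scores = U, rotations = R,
                 coef_by_lv = coef_by_lv, b = coef_by_lv[, n_lv],
                 x_mean = x_mean, y_mean = y_mean,
                 explained_x_variance = expl, threshold = threshold,
                 wavenumbers = train$wavenumbers,
                 class_coding = c(negative = negative, positive = positive),
                 mode = train$mode),
            class = "plsda_model")
}

#' Predict scores and classes from a PLS-DA model
#'
#' The score is `yhat = (x - x_mean) b + y_mean`; rows with
#' `yhat >= threshold` are assigned the positive class (a tie at the
#' threshold breaks toward the positive class, by convention).
#'
#' @param object A `plsda_model`.
#' @param set A `spectrum_set` on the model grid with the same
#'   preprocessing.
#' @param ncomp Number of latent variables to use (default all).
#' @param ... Unused.
#' @return A data frame with `score`, `class` and `side`
#'   (`score - threshold`, the signed distance to the discrimination
#'   line); x-block scores as attribute `"x_scores"`.
#' @export
predict.plsda_model <- function(object, set, ncomp = object$n_lv, ...) {
  x <- if (inherits(set, "spectrum_set")) {
    check_same_grid(object$wavenumbers, set$wavenumbers)
    set$x
  } else as.matrix(set)
  if (ncol(x) != length(object$x_mean)) {
    stop("set is not on the model's wavenumber grid", call. = FALSE)
  }
  stopifnot(ncomp >= 1, ncomp <= object$n_lv)
  xc <- sweep(x, 2, object$x_mean)
  score <- drop(xc %*% object$coef_by_lv[, ncomp]) + object$y_mean
  cls <- ifelse(score >= object$threshold,
                object$class_coding[["positive"]],
                object$class_coding[["negative"]])
  out <- data.frame(score = score, class = cls,
                    side = score - object$threshold)
  attr(out, "x_scores") <- xc %*% object$rotations[, seq_len(ncomp),
                                                   drop = FALSE]
  out
}

#' Choose the number of latent variables by cross-validated error
#'
#' For each candidate LV count, computes the average calibration
#' (resubstitution) and cross-validation misclassification error under
#' the supplied folds, and picks the smallest count achieving the
#' minimum CV error.
#'
#' @param train A `spectrum_set`.
#' @param labels Class labels; defaults to `train$meta$class`.
#' @param folds Per-row fold indices (e.g. from [venetian_blinds()]).
#' @param max_lv Largest LV count considered (capped by fold sizes).
#' @param ... Passed to [fit_plsda()].
#' @return List with `n_lv`, `cv_error` and `cal_error` (length
#'   `max_lv`).
#' @export
select_n_lv <- function(train, labels = NULL, folds, max_lv = 10, ...) {
  stopifnot(max_lv >= 1)
  if (is.null(labels)) labels <- train$meta$class
  n <- n_spectra(train)
  cal_model <- fit_plsda(train, labels, n_lv = min(max_lv, n - 1), ...)
  navail <- cal_model$n_lv
  cal_error <- cv_error <- rep(NA_real_, max_lv)
  pos <- cal_model$class_coding[["positive"]]
  truth <- labels == pos
  for (a in seq_len(min(max_lv, navail))) {
    pr <- predict(cal_model, train, ncomp = a)
    cal_error[a] <- mean((pr$class == pos) != truth)
  }
  cv_pred <- matrix(NA_real_, n, max_lv)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    m <- fit_plsda(subset_rows(train, !hold), labels[!hold],
                   n_lv = min(max_lv, sum(!hold) - 1), ...)
    for (a in seq_len(min(max_lv, m$n_lv))) {
      cv_pred[hold, a] <- predict(m, subset_rows(train, hold), ncomp = a)$score
    }
  }
  for (a in seq_len(max_lv)) {
    if (!anyNA(cv_pred[, a])) {
      cv_error[a] <- mean((cv_pred[, a] >= cal_model$threshold) != truth)
    }
  }
  ok <- which(!is.na(cv_error))
  n_lv <- ok[which.min(cv_error[ok])]          # smallest index at minimum
  list(n_lv = n_lv, cv_error = cv_error, cal_error = cal_error)
}

#' Per-latent-variable explained X variance
#'
#' Percent of the centered X sum of squares captured by each latent
#' variable, `100 * ||t_a p_a'||^2 / ||Xc||^2`.
#'
#' @param model A fitted `plsda_model`.
#' @return Numeric vector, one entry per LV; entries are nonnegative and
#'   sum to at most 100.
#' @export
explained_variance <- function(model) model$explained_x_variance

#' Extract feature bands from latent-variable loadings
#'
#' Local extrema of the selected X-block loadings whose absolute value
#' is at least `prominence_fraction` of that loading's maximum absolute
#' value, reported with their sign -- the loading-derived spectral
#' biomarkers.
#'
#' @param model A fitted `plsda_model`.
#' @param lv_indices Which latent variables to scan (default 1:2).
#' @param prominence_fraction Minimum |loading| relative to the LV's max
#'   (default 0.1).
#' @return Data frame with `wavenumber`, `sign`, `lv_index`,
#'   `loading_value`, ordered by LV then descending |loading|.
#' @export
extract_feature_bands <- function(model, lv_indices = 1:2,
                                  prominence_fraction = 0.1) {
  stopifnot(all(lv_indices >= 1), all(lv_indices <= model$n_lv))
  out <- list()
  wn <- model$wavenumbers
  for (lv in lv_indices) {
    v <- model$x_loadings[, lv]
    mx <- max(abs(v))
    if (mx == 0) next
    n <- length(v)
    if (n < 3) next
    interior <- 2:(n - 1)
    is_ext <- (abs(v[interior]) > abs(v[interior - 1]) &
                 abs(v[interior]) >= abs(v[interior + 1])) &
      abs(v[interior]) >= prominence_fraction * mx
    idx <- interior[is_ext]
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        wavenumber = wn[idx],
        sign = ifelse(v[idx] >= 0, "+", "-"),
        lv_index = lv, loading_value = v[idx])
    }
  }
  if (!length(out)) {
    return(data.frame(wavenumber = numeric(0), sign = character(0),
                      lv_index = integer(0), loading_value = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lv_index, -abs(res$loading_value)), ]
  rownames(res) <- NULL
  res
}

#' Literature band assignments for the fingerprint region
#'
#' Static lookup of vibrational modes and biochemical assignments for the
#' discriminative bands commonly reported in oral-tissue FTIR work. These
#' annotations are reference knowledge, not a computation.
#'
#' @return Data frame with `wavenumber` (cm^-1) and `assignment`.
#' @export
band_annotations <- function() {
  data.frame(
    wavenumber = c(1704, 1670, 1660, 1654, 1640, 1548, 1516, 1482, 1238,
                   1082, 1026, 966),
    assignment = c(
      "Ester carbonyl C=O stretching; fatty acid esters, lipids",
      "Amide I; protein secondary structure",
      "Amide I; protein secondary structure",
      "Amide I C=O stretching; protein secondary structure",
      "Amide I; protein secondary structure",
      "Amide II C-N / N-H; protein secondary structure",
      "Amide II; protein secondary structure",
      "CH3 deformation; lipid",
      "Asymmetric phosphodiester stretching (PO2-); nucleic acid, lipid, amide III",
      "Symmetric phosphodiester stretching (PO2-); DNA, phospholipid, collagen",
      "C-O stretching of carbohydrate CH2OH (glucose, glycogen)",
      "C-O stretching of phosphodiester / deoxyribose; DNA"),
    stringsAsFactors = FALSE)
}

#' Annotate extracted feature bands with literature assignments
#'
#' Joins each extracted band to the nearest annotated wavenumber within
#' `max_distance`; unmatched bands get `NA`.
#'
#' @param bands Output of [extract_feature_bands()].
#' @param max_distance Largest allowed distance in cm^-1 (default 8).
#' @return `bands` with an `assignment` column.
#' @export
annotate_bands <- function(bands, max_distance = 8) {
  ann <- band_annotations()
  bands$assignment <- vapply(bands$wavenumber, function(wn) {
    d <- abs(ann$wavenumber - wn)
    if (min(d) <= max_distance) ann$assignment[which.min(d)] else NA_character_
  }, character(1))
  bands
}
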