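#' Fit a PCA model, X = t p' + E
#'
#' Mean-centered principal component analysis via [stats::prcomp()]. When
#' `n_components` is `NULL`, the smallest number of components explaining
#' at least `var_target` of the variance is retained, capped at `max_k`
#' and at the numerical rank.
#'
#' @param set A `spectrum_set` (or numeric matrix).
#' @param n_components Number of components, or `NULL` for the rule above.
#' @param var_target Cumulative explained-variance target (default 0.95).
#' @param max_k Cap on the automatic component count (default 10).
#' @return A `pca_model`: `mean`, `loadings` (wavenumbers x k), `scores`
#'   (rows x k), `eigenvalues` (all score variances, not just retained),
#'   `n_components`, `n` (training rows), `explained_variance` (%).
#' @export
fit_pca <- function(set, n_components = NULL, var_target = 0.95, max_k = 10) {
  x <- if (inherits(set, "spectrum_set")) set$x else as.matrix(set)
  n <- nrow(x); p <- ncol(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev[1], 0) * 1e-12)
  if (is.null(n_components)) {
    if (rank == 0L) {
      k <- 0L
    } else {
      cum <- cumsum(ev) / sum(ev)
      k <- min(which(cum >= var_target), max_k, rank)
    }
  } else {
    if (n_components > min(n, p)) {
      stop("n_components (", n_components, ") exceeds min(rows, cols) = ",
           min(n, p), call. = FALSE)
    }
    k <- as.integer(n_components)
  }
  structure(list(mean = pc$center,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 eigenvalues = ev, n_components = k, n = n,
                 explained_variance = if (sum(ev) > 0) 100 * ev / sum(ev)
                                      else ev),
            class = "pca_model")
}

# 95% confidence limit for Hotelling T2 with k PCs and n training rows
t2_limit <- function(k, n, alpha = 0.95) {
  if (n <= k) stop("need more training rows than components for the T2 limit",
                   call. = FALSE)
  k * (n - 1) / (n - k) * stats::qf(alpha, k, n - k)
}

# Jackson-Mudholkar 95% limit for the Q residual, from the residual
# eigenvalues (those beyond the retained components)
q_limit <- function(resid_ev, alpha = 0.95) {
  th1 <- sum(resid_ev); th2 <- sum(resid_ev^2); th3 <- sum(resid_ev^3)
  if (th1 <= 0) return(0)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  ca <- stats::qnorm(alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Reduced Hotelling T2 and Q residual statistics
#'
#' For each row: T2 is the sum of squared scores normalized by the
#' per-component score variance over the retained components; Q is the
#' squared norm of the off-model residual. Each is divided by its 95%
#' confidence limit (T2 via the F-distribution relation, Q via the
#' Jackson-Mudholkar approximation) to give "reduced" values, so 1 marks
#' the 95% boundary.
#'
#' @param model A `pca_model`.
#' @param set A `spectrum_set` (or matrix) on the model grid.
#' @param tau_t,tau_q Reduced-statistic thresholds above which a row is
#'   flagged as an outlier (default 3).
#' @return A data frame (`outlier_report`): `reduced_t2`, `reduced_q`,
#'   `is_outlier`, with the thresholds and limits as attributes.
#' @export
t2_q <- function(model, set, tau_t = 3, tau_q = 3) {
  x <- if (inherits(set, "spectrum_set")) set$x else as.matrix(set)
  if (ncol(x) != length(model$mean)) {
    stop("set is not on the model grid", call. = FALSE)
  }
  k <- model$n_components
  xc <- sweep(x, 2, model$mean)
  if (k == 0L) {
    t2 <- rep(0, nrow(x)); q <- rowSums(xc^2)
    rt2 <- t2
    ql <- 0
    rq <- ifelse(q <= 1e-12, 0, Inf)
    tl <- Inf
  } else {
    ev <- model$eigenvalues[seq_len(k)]
    if (any(ev <= 0)) stop("zero eigenvalue among retained components",
                           call. = FALSE)
    scores <- xc %*% model$loadings
    t2 <- drop(scores^2 %*% (1 / ev))
    resid <- xc - tcrossprod(scores, model$loadings)
    q <- rowSums(resid^2)
    tl <- t2_limit(k, model$n)
    rt2 <- t2 / tl
    resid_ev <- model$eigenvalues[-seq_len(k)]
    ql <- q_limit(resid_ev)
    rq <- if (ql > 0) q / ql else ifelse(q <= 1e-10 * max(1, sum(ev)), 0, Inf)
  }
  rep <- data.frame(reduced_t2 = rt2, reduced_q = rq,
                    is_outlier = rt2 > tau_t | rq > tau_q)
  attr(rep, "tau_t") <- tau_t
  attr(rep, "tau_q") <- tau_q
  attr(rep, "t2_limit") <- tl
  attr(rep, "q_limit") <- ql
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Remove outlier pixels by the reduced T2 / Q rule
#'
#' Fits a PCA model (unless one is supplied) and drops every row whose
#' reduced T2 or reduced Q exceeds its threshold.
#'
#' @param set A `spectrum_set`.
#' @param model Optional pre-fitted `pca_model`; `NULL` fits one on `set`.
#' @param tau_t,tau_q Reduced-statistic thresholds (default 3; `Inf`
#'   disables removal).
#' @return List with `set` (rows kept) and `report` (the full
#'   `outlier_report`).
#' @export
remove_outliers <- function(set, model = NULL, tau_t = 3, tau_q = 3) {
  stopifnot(tau_t > 0, tau_q > 0)
  if (is.null(model)) model <- fit_pca(set)
  rep <- t2_q(model, set, tau_t, tau_q)
  list(set = subset_rows(set, !rep$is_outlier), report = rep)
}

#' Agglomerative hierarchical clustering of spectra
#'
#' Ward linkage on Euclidean distances by default, the usual chemometrics
#' choice for separating tissue types whose spectra differ in shape.
#'
#' @param set A `spectrum_set` with >= 2 rows.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return An `hclust` tree (merge history + heights).
#' @export
hca <- function(set, linkage = "ward.D2", metric = "euclidean") {
  x <- if (inherits(set, "spectrum_set")) set$x else as.matrix(set)
  if (nrow(x) < 2) stop("need at least 2 rows for clustering", call. = FALSE)
  d <- if (metric == "euclidean") {
    # Gram-matrix route: much faster than stats::dist for wide matrices
    sq <- rowSums(x^2)
    d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
    d2[d2 < 0] <- 0
    stats::as.dist(sqrt(d2))
  } else {
    stats::dist(x, method = metric)
  }
  stats::hclust(d, method = linkage)
}

#' Cut a cluster tree into k groups
#' @param tree An `hclust` tree.
#' @param k Number of clusters.
#' @return Integer cluster labels.
#' @export
cut_k <- function(tree, k) stats::cutree(tree, k = k)

#' Select the epithelial pixels of an area
#'
#' Cuts the tree at k = 2 and keeps the cluster designated epithelial:
#' by default the majority cluster (imaging areas are placed primarily in
#' epithelium), overridable to the minority cluster or an explicit
#' cluster id. The split is only applied when the top merge is markedly
#' higher than the rest of the tree (`min_split_ratio` times the
#' second-highest merge); otherwise the area is treated as homogeneous
#' epithelium and all rows are returned.
#'
#' @param area_set A `spectrum_set` for one area (outliers removed).
#' @param tree Optional `hclust` tree; `NULL` computes [hca()].
#' @param designate `"majority"`, `"minority"`, or a cluster id (1 or 2).
#' @param min_split_ratio Top-height / second-height ratio below which no
#'   split is made (default 3).
#' @return The epithelial subset of `area_set`.
#' @export
select_epithelium <- function(area_set, tree = NULL, designate = "majority",
                              min_split_ratio = 3) {
  n <- n_spectra(area_set)
  if (n < 2) return(area_set)
  if (is.null(tree)) tree <- hca(area_set)
  h <- sort(tree$height, decreasing = TRUE)
  if (length(h) < 2 || h[1] <= 0 || h[1] < min_split_ratio * h[2]) {
    return(area_set)
  }
  cl <- cut_k(tree, 2)
  counts <- tabulate(cl, 2)
  keep <- if (identical(designate, "majority")) which.max(counts)
          else if (identical(designate, "minority")) which.min(counts)
          else as.integer(designate)
  subset_rows(area_set, cl == keep)
}

#' Representative spectrum of an imaging area
#'
#' Column-wise mean of the (QC-passed, epithelial) pixel spectra; the
#' result carries the area's sample id, area id and class with role
#' `"representative"`.
#'
#' @param epithelial_set A `spectrum_set` with >= 1 row, one area.
#' @return A single-row `spectrum_set`.
#' @export
representative_spectrum <- function(epithelial_set) {
  if (n_spectra(epithelial_set) < 1) stop("empty set", call. = FALSE)
  m <- epithelial_set$meta[1, , drop = FALSE]
  m$role <- "representative"
  m$tissue <- "epithelium"
  spectrum_set(epithelial_set$wavenumbers,
               matrix(colMeans(epithelial_set$x), nrow = 1),
               m, epithelial_set$mode)
}

#' Select the two most heterogeneous representatives per sample
#'
#' For each sample, retains the pair of area representatives with maximal
#' Euclidean distance -- a deterministic proxy for "the two spectra that
#' best reflect intra-sample heterogeneity". Ties break toward the
#' lexicographically first area pair.
#'
#' @param representatives A `spectrum_set` of area representatives
#'   (>= 2 per sample).
#' @return A `spectrum_set` with exactly 2 rows per sample, ordered by
#'   sample id.
#' @export
select_two_per_sample <- function(representatives) {
  ids <- representatives$meta$sample_id
  out <- list()
  for (sid in sort(unique(ids))) {
    idx <- which(ids == sid)
    idx <- idx[order(representatives$meta$area_id[idx])]
    if (length(idx) < 2) {
      stop("sample ", sid, " has only ", length(idx),
           " area representative(s); generate at least 2 areas per sample",
           call. = FALSE)
    }
    if (length(idx) == 2) {
      best <- idx
    } else {
      d <- as.matrix(stats::dist(representatives$x[idx, , drop = FALSE]))
      pair <- which(d == max(d), arr.ind = TRUE)
      pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE][1, ]
      best <- idx[sort(pair)]
    }
    out[[sid]] <- subset_rows(representatives, best)
  }
  bind_spectra(out)
}

#' Class-average spectrum
#'
#' @param representatives A `spectrum_set`.
#' @param class Class label (`"H"`, `"D"` or `"C"`).
#' @return A single-row `spectrum_set`, the mean over that class, with
#'   attribute `n_averaged`.
#' @export
class_average <- function(representatives, class) {
  idx <- which(representatives$meta$class == class)
  if (!length(idx)) stop("no rows of class ", class, call. = FALSE)
  out <- spectrum_set(representatives$wavenumbers,
                      matrix(colMeans(representatives$x[idx, , drop = FALSE]),
                             nrow = 1),
                      data.frame(sample_id = paste0("avg_", class),
                                 class = class, role = "representative"),
                      representatives$mode)
  attr(out, "n_averaged") <- length(idx)
  out
}

#' Persist an outlier report as CSV
#' @param report An `outlier_report` from [t2_q()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  df <- as.data.frame(report)
  df$tau_t <- attr(report, "tau_t")
  df$tau_q <- attr(report, "tau_q")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Persist a cluster tree as a JSON merge list
#'
#' Stores the agglomeration history: each entry gives the pair merged
#' (negative = leaf index, positive = earlier merge) and its height,
#' plus the leaf order.
#'
#' @param tree An `hclust` tree.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_tree <- function(tree, path) {
  jsonlite::write_json(
    list(merge = apply(tree$merge, 1, identity, simplify = FALSE),
         height = tree$height, order = tree$order,
         method = tree$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
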