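#' Preprocessing configuration
#'
#' Parameters of the signal-correction chain, applied in the fixed order:
#' absorbance conversion, fingerprint selection, Savitzky-Golay smoothing,
#' EMSC scatter correction, AWLS baseline correction, vector
#' normalization, then (optionally, for model building) a 7-point
#' second-derivative step followed by re-normalization.
#'
#' @param region `c(high, low)` fingerprint bounds in cm^-1.
#' @param smooth_window Odd smoothing window in points (> `smooth_polyorder`).
#' @param smooth_polyorder Smoothing polynomial order.
#' @param emsc_reference Reference spectrum for EMSC, or `NULL` to use the
#'   mean of the set being corrected.
#' @param emsc_poly_order Order of the EMSC polynomial background terms.
#' @param awls_poly_order Baseline polynomial order (<= 4).
#' @param awls_max_iter Maximum reweighting iterations.
#' @param awls_tol Convergence threshold on the baseline change.
#' @param derivative_window,derivative_polyorder Second-derivative
#'   Savitzky-Golay window (7 points) and polynomial order.
#' @param apply_derivative Apply the derivative step after normalization.
#' @param step_order Names of the chain steps in order; any permutation of
#'   the canonical order is rejected (the chain is order-sensitive).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(region = c(1800, 950),
                              smooth_window = 9, smooth_polyorder = 2,
                              emsc_reference = NULL, emsc_poly_order = 2,
                              awls_poly_order = 2, awls_max_iter = 300,
                              awls_tol = 5e-5,
                              derivative_window = 7, derivative_polyorder = 3,
                              apply_derivative = FALSE,
                              step_order = preprocess_steps()) {
  stopifnot(length(region) == 2, smooth_window %% 2 == 1,
            smooth_window > smooth_polyorder, emsc_poly_order >= 0,
            awls_poly_order <= 4, awls_max_iter >= 1,
            derivative_window %% 2 == 1,
            derivative_window > derivative_polyorder)
  if (!identical(as.character(step_order), preprocess_steps())) {
    stop("the preprocessing chain is order-sensitive; step_order must be: ",
         paste(preprocess_steps(), collapse = " -> "), call. = FALSE)
  }
  structure(list(region = sort(as.numeric(region), decreasing = TRUE),
                 smooth_window = as.integer(smooth_window),
                 smooth_polyorder = as.integer(smooth_polyorder),
                 emsc_reference = emsc_reference,
                 emsc_poly_order = as.integer(emsc_poly_order),
                 awls_poly_order = as.integer(awls_poly_order),
                 awls_max_iter = as.integer(awls_max_iter),
                 awls_tol = awls_tol,
                 derivative_window = as.integer(derivative_window),
                 derivative_polyorder = as.integer(derivative_polyorder),
                 apply_derivative = isTRUE(apply_derivative),
                 step_order = preprocess_steps()),
            class = "preprocess_config")
}

#' Canonical order of the preprocessing chain
#' @return Character vector of step names.
#' @export
preprocess_steps <- function() {
  c("absorbance", "fingerprint", "savgol", "emsc", "awls", "vector_normalize")
}

#' Transmission to absorbance conversion, A = log10(1/T)
#'
#' @param set A `spectrum_set` in transmission mode with all values > 0.
#' @return The set in absorbance mode.
#' @export
transmittance_to_absorbance <- function(set) {
  if (set$mode != "transmission") {
    stop("expected transmission mode, got ", set$mode, call. = FALSE)
  }
  bad <- which(set$x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive transmission at row %d, column %d (%.6g)",
                 bad[1, 1], bad[1, 2], set$x[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  spectrum_set(set$wavenumbers, -log10(set$x), set$meta, "absorbance")
}

#' Restrict a set to the fingerprint region
#'
#' @param set A `spectrum_set`.
#' @param region `c(high, low)` bounds in cm^-1 (order-free).
#' @return The set with columns outside the region dropped; grid order
#'   preserved.
#' @export
select_fingerprint <- function(set, region = c(1800, 950)) {
  lo <- min(region); hi <- max(region)
  keep <- set$wavenumbers >= lo & set$wavenumbers <= hi
  if (!any(keep)) stop("region [", lo, ", ", hi, "] is outside the grid",
                       call. = FALSE)
  spectrum_set(set$wavenumbers[keep], set$x[, keep, drop = FALSE],
               set$meta, set$mode)
}

# Savitzky-Golay projection matrix on an npts grid with spacing h.
# Interior rows: central least-squares filter. Edge rows: polynomial fit
# of the first/last full window, evaluated (or differentiated) at the
# edge point itself, so interior values match the sliding-polyfit oracle
# exactly and edges use constant-window extrapolation.
savgol_matrix <- function(npts, window, polyorder, deriv, h) {
  if (window >= npts) stop("window (", window, ") must be smaller than the ",
                           "spectrum length (", npts, ")", call. = FALSE)
  k <- (window - 1L) %/% 2L
  S <- matrix(0, npts, npts)
  fit_row <- function(offsets, at) {
    # derivative of the local LS polynomial at position `at` (in points)
    V <- outer(offsets, 0:polyorder, `^`)
    G <- solve(crossprod(V), t(V))          # coefs = G %*% y
    dcoef <- numeric(polyorder + 1)
    for (j in deriv:polyorder) {
      dcoef[j + 1] <- prod(seq(j, by = -1, length.out = deriv)) *
        at^(j - deriv)
    }
    if (deriv == 0) dcoef <- at^(0:polyorder)
    drop(dcoef %*% G) / h^deriv
  }
  central <- fit_row(-k:k, 0)
  for (i in seq_len(npts)) {
    if (i <= k) {
      S[i, 1:window] <- fit_row(0:(window - 1L), i - 1L)
    } else if (i > npts - k) {
      S[i, (npts - window + 1L):npts] <- fit_row(-(window - 1L):0,
                                                 i - npts)
    } else {
      S[i, (i - k):(i + k)] <- central
    }
  }
  S
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Sliding local polynomial least squares per row. Interior points equal
#' the exact windowed polynomial fit evaluated at the window center; edge
#' points use the polynomial fit of the first/last full window. The
#' derivative is scaled by the grid spacing so it is a derivative with
#' respect to wavenumber; only even derivative orders (0, 2) are
#' supported on the descending grid.
#'
#' @param set A `spectrum_set` on a uniform grid.
#' @param window Odd window length in points.
#' @param polyorder Polynomial order (< window).
#' @param deriv_order 0 (smoothing) or 2 (second derivative).
#' @return The filtered set; mode becomes `"derivative"` when
#'   `deriv_order > 0`.
#' @export
savgol <- function(set, window = 9, polyorder = 2, deriv_order = 0) {
  stopifnot(window %% 2 == 1, window > polyorder, deriv_order %in% c(0, 2))
  h <- abs(diff(set$wavenumbers))
  if (diff(range(h)) > 1e-8 * mean(h)) stop("grid must be uniform", call. = FALSE)
  S <- savgol_matrix(ncol(set$x), window, polyorder, deriv_order, mean(h))
  spectrum_set(set$wavenumbers, tcrossprod(set$x, S), set$meta,
               if (deriv_order > 0) "derivative" else set$mode)
}

# Legendre polynomials up to `order` on z in [-1, 1]; columns 1..order
legendre_basis <- function(z, order) {
  if (order < 1) return(matrix(0, length(z), 0))
  P <- matrix(0, length(z), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- z
  if (order >= 2) for (n in 1:(order - 1)) {
    P[, n + 2] <- ((2 * n + 1) * z * P[, n + 1] - n * P[, n]) / (n + 1)
  }
  P[, -1, drop = FALSE]
}

#' Extended multiplicative signal correction
#'
#' Least-squares fit of each row `s` against an additive offset, the
#' reference spectrum `m`, and Legendre polynomial background terms:
#' `s ~ a + b*m + sum_i d_i P_i(z)`; the corrected row is
#' `(s - a - sum_i d_i P_i) / b`. Rows whose multiplicative coefficient
#' `b` falls below 1e-8 are returned uncorrected and flagged (attribute
#' `"emsc_flagged"`, plus a warning).
#'
#' @param set A `spectrum_set`.
#' @param reference Reference spectrum on the same grid; `NULL` means the
#'   column mean of `set`.
#' @param poly_order Order of the polynomial background (>= 0).
#' @return The corrected set, with attribute `emsc_flagged` (row indices).
#' @export
emsc <- function(set, reference = NULL, poly_order = 2) {
  stopifnot(poly_order >= 0)
  if (is.null(reference)) reference <- colMeans(set$x)
  if (length(reference) != ncol(set$x)) {
    stop("reference is not on the set's grid", call. = FALSE)
  }
  g <- set$wavenumbers
  z <- if (length(g) > 1) 2 * (g - min(g)) / (max(g) - min(g)) - 1 else 0
  M <- cbind(1, reference, legendre_basis(z, poly_order))
  qrM <- qr(M)
  B <- t(qr.coef(qrM, t(set$x)))              # rows x (2 + poly_order)
  b <- B[, 2]
  flagged <- which(b < 1e-8)
  bg <- B[, -2, drop = FALSE] %*% t(M[, -2, drop = FALSE])
  corrected <- (set$x - bg) / b
  if (length(flagged)) {
    corrected[flagged, ] <- set$x[flagged, , drop = FALSE]
    warning(length(flagged), " row(s) with near-zero EMSC scale left uncorrected")
  }
  out <- spectrum_set(set$wavenumbers, corrected, set$meta, set$mode)
  attr(out, "emsc_flagged") <- flagged
  out
}

#' Automated weighted least-squares baseline correction
#'
#' Iterative asymmetric polynomial baseline estimate: fit a polynomial,
#' clip the signal to the fit (points above the current baseline stop
#' pulling it upward -- the asymmetric reweighting), refit, and iterate
#' until the baseline stops moving (`tol`, or `max_iter` with a
#' warning). The baseline sequence is monotone non-increasing, so the
#' iteration always converges; the converged baseline is subtracted.
#'
#' @param set A `spectrum_set`.
#' @param poly_order Baseline polynomial order (<= 4).
#' @param max_iter Maximum iterations.
#' @param tol Convergence threshold on the maximum baseline change
#'   between iterations, in absorbance units, scaled per row by the
#'   row's absorbance magnitude (floored at 1). The default (5e-5) sits
#'   two orders of magnitude below typical spectral noise, where the
#'   baseline is stationary for all practical purposes.
#' @return The baseline-corrected set, with attribute `awls_baseline`
#'   (the subtracted baselines) for inspection.
#' @export
awls_baseline <- function(set, poly_order = 2, max_iter = 300, tol = 5e-5) {
  stopifnot(poly_order >= 0, poly_order <= 4, max_iter >= 1, tol >= 0)
  g <- set$wavenumbers
  z <- if (length(g) > 1) 2 * (g - min(g)) / (max(g) - min(g)) - 1 else 0
  V <- outer(z, 0:poly_order, `^`)
  Q <- qr.Q(qr(V))                             # orthonormal basis, stable
  x <- set$x
  n <- nrow(x)
  target <- x
  baselines <- matrix(Inf, n, ncol(x))
  active <- rep(TRUE, n)
  row_tol <- tol * pmax(1, apply(abs(x), 1, max))
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    # unweighted LS fit of the clipped signal: Q orthonormal, so the
    # coefficient matrix is a single cross product
    bl <- tcrossprod(target[idx, , drop = FALSE] %*% Q, Q)
    dbl <- abs(bl - baselines[idx, , drop = FALSE])
    moved <- dbl[cbind(seq_along(idx), max.col(dbl))] > row_tol[idx]
    baselines[idx, ] <- bl
    target[idx, ] <- pmin(x[idx, , drop = FALSE], bl)
    active[idx] <- moved
  }
  if (any(active)) warning("AWLS did not converge within max_iter for ",
                           sum(active), " row(s); last iterate used")
  out <- spectrum_set(set$wavenumbers, x - baselines, set$meta, set$mode)
  attr(out, "awls_baseline") <- baselines
  out
}

#' Euclidean vector normalization
#'
#' Each row is divided by its L2 norm over the retained region.
#'
#' @param set A `spectrum_set` with no all-zero rows.
#' @param on_zero What to do with zero-norm rows: `"error"` (default,
#'   naming the rows) or `"drop"` (remove them -- such rows are
#'   information-free, e.g. fully clipped outlier pixels).
#' @return The normalized set.
#' @export
vector_normalize <- function(set, on_zero = c("error", "drop")) {
  on_zero <- match.arg(on_zero)
  nrm <- sqrt(rowSums(set$x^2))
  zero <- which(nrm < 1e-300)
  if (length(zero)) {
    if (on_zero == "error") {
      stop("zero-norm row(s): ", paste(zero, collapse = ", "), call. = FALSE)
    }
    set <- subset_rows(set, -zero)
    nrm <- nrm[-zero]
  }
  spectrum_set(set$wavenumbers, set$x / nrm, set$meta, set$mode)
}

#' Run the full preprocessing chain
#'
#' Applies, in this order: absorbance conversion (skipped when the input
#' is already absorbance), fingerprint selection, Savitzky-Golay
#' smoothing, EMSC, AWLS baseline correction and vector normalization;
#' when `cfg$apply_derivative` is set, a second-derivative
#' Savitzky-Golay step followed by re-normalization (differentiation
#' destroys the unit norm).
#'
#' @param set A `spectrum_set` in transmission (or absorbance) mode.
#' @param cfg A [preprocess_config()].
#' @param on_zero Handling of zero-norm rows at the normalization steps
#'   (see [vector_normalize()]); the pipeline uses `"drop"` for raw
#'   pixel data, where a fully clipped outlier pixel carries no signal.
#' @return The preprocessed set.
#' @export
preprocess_general <- function(set, cfg = preprocess_config(),
                               on_zero = "error") {
  if (set$mode == "derivative") {
    stop("input is already derivative mode", call. = FALSE)
  }
  if (set$mode == "transmission") set <- transmittance_to_absorbance(set)
  set <- select_fingerprint(set, cfg$region)
  set <- savgol(set, cfg$smooth_window, cfg$smooth_polyorder, 0)
  set <- emsc(set, cfg$emsc_reference, cfg$emsc_poly_order)
  set <- awls_baseline(set, cfg$awls_poly_order, cfg$awls_max_iter, cfg$awls_tol)
  set <- vector_normalize(set, on_zero)
  if (cfg$apply_derivative) {
    set <- savgol(set, cfg$derivative_window, cfg$derivative_polyorder, 2)
    set <- vector_normalize(set, on_zero)
  }
  set
}
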