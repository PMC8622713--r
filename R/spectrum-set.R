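#' Spectrum set: the pipeline's shared spectral container
#'
#' A `spectrum_set` bundles a wavenumber grid, a matrix of spectra
#' (rows = spectra, columns = wavenumbers) and per-row provenance
#' metadata. Every pipeline stage consumes and returns this container.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone. Ascending input is re-sorted to the canonical descending
#'   order (and the matrix columns with it).
#' @param x Numeric matrix, one row per spectrum, `length(wavenumbers)`
#'   columns.
#' @param meta Data frame with one row per spectrum. Must contain
#'   `sample_id`; columns `area_id`, `class` (one of `"H"`, `"D"`,
#'   `"C"`), `role` (`"pixel"` or `"representative"`) and `tissue`
#'   are filled with `NA` when absent.
#' @param mode Character scalar: `"transmission"`, `"absorbance"` or
#'   `"derivative"`. Mode transitions are only ever
#'   transmission -> absorbance -> derivative.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavenumbers`, `x`, `meta`, `mode`.
#' @export
spectrum_set <- function(wavenumbers, x, meta, mode = "absorbance") {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(wavenumbers)) {
    stop("matrix has ", ncol(x), " columns but grid has ",
         length(wavenumbers), " wavenumbers", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (length(d) && any(d == 0)) stop("wavenumber grid has duplicates", call. = FALSE)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  resorted <- FALSE
  if (length(d) && all(d > 0)) {  # canonicalize to descending
    ord <- order(wavenumbers, decreasing = TRUE)
    wavenumbers <- wavenumbers[ord]
    x <- x[, ord, drop = FALSE]
    resorted <- TRUE
  }
  mode <- match.arg(mode, c("transmission", "absorbance", "derivative"))
  if (missing(meta) || is.null(meta)) {
    meta <- data.frame(sample_id = rep(NA_character_, nrow(x)))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(x)) {
    stop("meta has ", nrow(meta), " rows but matrix has ", nrow(x), call. = FALSE)
  }
  if (!"sample_id" %in% names(meta)) stop("meta must contain sample_id", call. = FALSE)
  for (col in c("area_id", "class", "role", "tissue")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  rownames(meta) <- NULL
  dimnames(x) <- NULL
  out <- structure(list(wavenumbers = wavenumbers, x = x, meta = meta,
                        mode = mode),
                   class = "spectrum_set")
  if (resorted) attr(out, "resorted_from_ascending") <- TRUE
  out
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavenumbers [%.0f..%.0f cm-1], mode=%s\n",
              nrow(x$x), ncol(x$x), max(x$wavenumbers), min(x$wavenumbers), x$mode))
  cls <- table(x$meta$class, useNA = "ifany")
  cat("  classes:", paste(names(cls), as.integer(cls), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(set) nrow(set$x)

#' Row-subset a spectrum set
#' @param set A `spectrum_set`.
#' @param i Row index (logical or integer).
#' @return A `spectrum_set` with the selected rows.
#' @export
subset_rows <- function(set, i) {
  spectrum_set(set$wavenumbers, set$x[i, , drop = FALSE],
               set$meta[i, , drop = FALSE], set$mode)
}

#' Stack spectrum sets row-wise
#'
#' All sets must share the same grid and mode.
#' @param ... `spectrum_set` objects, or a single list of them.
#' @return One combined `spectrum_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "spectrum_set")) sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  g <- sets[[1L]]$wavenumbers
  mode <- sets[[1L]]$mode
  for (s in sets) {
    if (!isTRUE(all.equal(s$wavenumbers, g))) stop("grids differ", call. = FALSE)
    if (s$mode != mode) stop("modes differ", call. = FALSE)
  }
  spectrum_set(g, do.call(rbind, lapply(sets, `[[`, "x")),
               do.call(rbind, lapply(sets, `[[`, "meta")), mode)
}

# shared internal check that two grids agree (used by model predict etc.)
check_same_grid <- function(a, b, what = "set") {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-8) {
    stop(what, " is not on the model's wavenumber grid", call. = FALSE)
  }
  invisible(TRUE)
}
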