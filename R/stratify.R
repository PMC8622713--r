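#' Stratify dysplasia samples by the side-of-discrimination-line rule
#'
#' Applies a trained HK-vs-OSCC model to the dysplasia (D) representative
#' spectra (two per sample) and grades each sample: `HK-grade` when both
#' scores lie below `threshold - delta`, `OSCC-grade` when both lie at or
#' above `threshold + delta` (the tie at the threshold breaks toward the
#' positive class, as in prediction), and `borderline` when the two
#' scores fall on opposite sides of the discrimination line or either
#' lies within `delta` of it. With the default `delta = 0` the rule is
#' purely side-based.
#'
#' @param model A fitted `plsda_model` (or any model honoring the
#'   prediction contract).
#' @param oed_set A `spectrum_set` with exactly 2 rows per sample,
#'   preprocessed identically to the training spectra.
#' @param delta Borderline half-width on the score scale (default 0).
#' @return A `stratification_result` data frame: one row per sample with
#'   `sample_id`, `grade`, `y1`, `y2`, `margin`
#'   (min distance of a score to the threshold) and `pair_distance`
#'   (|y1 - y2|, the intra-sample heterogeneity proxy). Grade counts are
#'   in attribute `"counts"`.
#' @export
stratify_oed <- function(model, oed_set, delta = 0) {
  stopifnot(delta >= 0)
  tab <- table(oed_set$meta$sample_id)
  if (any(tab != 2)) {
    stop("every sample must have exactly 2 representative spectra; ",
         "offending: ", paste(names(tab)[tab != 2], collapse = ", "),
         call. = FALSE)
  }
  pr <- predict(model, oed_set)
  thr <- model$threshold
  ids <- sort(unique(oed_set$meta$sample_id))
  res <- lapply(ids, function(sid) {
    y <- pr$score[oed_set$meta$sample_id == sid]
    on_c_side <- y >= thr
    near <- abs(y - thr) < delta
    grade <- if (any(near) || length(unique(on_c_side)) > 1) "borderline"
             else if (all(on_c_side)) "OSCC-grade" else "HK-grade"
    data.frame(sample_id = sid, grade = grade, y1 = y[1], y2 = y[2],
               margin = min(abs(y - thr)), pair_distance = abs(y[1] - y[2]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  counts <- c("HK-grade" = sum(res$grade == "HK-grade"),
              "OSCC-grade" = sum(res$grade == "OSCC-grade"),
              "borderline" = sum(res$grade == "borderline"))
  structure(res, counts = counts, threshold = thr, delta = delta,
            class = c("stratification_result", "data.frame"))
}

#' Tabulate a stratification result
#'
#' Per-sample rows with the grade, the two scores, the margin to the
#' discrimination line and the score pair distance (the "line length"
#' read off a discrimination plot: long lines mean high intra-sample
#' heterogeneity).
#'
#' @param result A `stratification_result`.
#' @return A plain data frame with those columns, plus the grade counts
#'   as attribute `"counts"`.
#' @export
stratification_report <- function(result) {
  if (!nrow(result)) stop("empty stratification result", call. = FALSE)
  out <- as.data.frame(result)
  attr(out, "counts") <- attr(result, "counts")
  out
}

#' @export
print.stratification_result <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<stratification_result>",
      paste(names(counts), counts, sep = "=", collapse = " "), "\n")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}
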