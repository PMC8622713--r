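# Small seeded fixtures shared across test files.

mk_set <- function(x, grid = NULL, mode = "absorbance", class = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(grid)) grid <- seq(1800, by = -2, length.out = ncol(x))
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(x))))
  if (!is.null(class)) meta$class <- class
  spectrum_set(grid, x, meta, mode)
}

rand_set <- function(n, p, seed = 1, mode = "absorbance") {
  set.seed(seed)
  mk_set(matrix(rnorm(n * p), n, p), mode = mode)
}

# a reduced cohort for fast unit tests: 3 HK + 3 OSCC + 2 OED samples
small_scenario <- function(...) {
  cohort_scenario(n_hk = 3, n_oscc = 3,
                  oed_ground_truth = c("HKlike", "OSCClike"),
                  areas_per_sample = 2, ...)
}

# a low-noise distortion with no outliers, for separability-focused tests
mild_distortion <- function() {
  distortion_config(scatter_scale_range = c(0.95, 1.05),
                    baseline_coeff_sd = c(0.01, 0.005, 0.002),
                    noise_sd = 0.002, outlier_pixel_fraction = 0)
}

# two representative spectra per sample, straight from clean profiles
# (skips the pixel stages) -- for discriminant/evaluation tests
clean_representatives <- function(n_hk = 6, n_oscc = 6, noise_sd = 0.01,
                                  seed = 1, derivative = TRUE) {
  set.seed(seed)
  g <- default_grid()
  profiles <- c(rep("HK", n_hk), rep("OSCC", n_oscc))
  ids <- c(sprintf("H-%02d", seq_len(n_hk)), sprintf("C-%02d", seq_len(n_oscc)))
  cls <- c(rep("H", n_hk), rep("C", n_oscc))
  rows <- list()
  for (i in seq_along(profiles)) {
    base <- build_clean_spectrum(profiles[i], grid = g)
    for (j in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[i], class = cls[i],
        t(base + rnorm(length(g), sd = noise_sd)))
    }
  }
  df <- do.call(rbind, rows)
  set <- spectrum_set(g, as.matrix(df[, -(1:2)]),
                      df[c("sample_id", "class")], "absorbance")
  set <- vector_normalize(set)
  if (derivative) set <- vector_normalize(savgol(set, 7, 3, 2))
  set
}
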