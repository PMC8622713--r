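#' Default fingerprint wavenumber grid
#'
#' 1800 to 950 cm^-1, descending, 2 cm^-1 spacing (426 points). The
#' instrument's 4 cm^-1 spectral resolution is represented by band widths
#' (FWHM >= 8 cm^-1), not by the grid spacing.
#'
#' @param high,low Region bounds in cm^-1.
#' @param by Grid spacing in cm^-1 (positive).
#' @return Numeric vector of wavenumbers, descending.
#' @export
default_grid <- function(high = 1800, low = 950, by = 2) seq(high, low, by = -abs(by))

synthetic_classes <- c("HK", "OED_HKlike", "OED_OSCClike", "OSCC", "STROMA")

#' Default synthetic band table
#'
#' Gaussian band model of deparaffinized oral epithelium and stroma in the
#' fingerprint region. Epithelial amplitudes encode the malignant-progression
#' orderings observed in tissue: amide I (1650), amide II (1548) and amide
#' III (1310) fall HK > OED > OSCC, while nucleic-acid phosphate (1240,
#' 1080, 966) and carbohydrate (1154, 1030) bands rise OSCC > OED > HK.
#' The two dysplasia profiles are convex mixtures of the HK and OSCC
#' anchors (`oed_mix` toward the nearer class), so every ordering is strict.
#' The amide II red shift of dysplastic/malignant tissue is realized as an
#' extra right-shoulder sub-band at 1548 minus the class shift. No band is
#' placed in 1750-1700 cm^-1: the free-lipid ester band is removed by
#' deparaffinization. Stroma is a distinct collagen-dominated profile.
#'
#' @param amideII_redshift Named shifts in cm^-1 for the red-shifted amide
#'   II shoulder, `c(OED = 8, OSCC = 14)`.
#' @param oed_mix Mixing weight of the nearer anchor class for the two
#'   dysplasia profiles (default 0.75).
#' @return Data frame with columns `center`, `fwhm` and one amplitude
#'   column per class (`HK`, `OED_HKlike`, `OED_OSCClike`, `OSCC`,
#'   `STROMA`), in absorbance units.
#' @export
default_band_table <- function(amideII_redshift = c(OED = 8, OSCC = 14),
                               oed_mix = 0.75) {
  stopifnot(all(amideII_redshift > 0), oed_mix > 0.5, oed_mix < 1)
  # epithelial anchor bands: center, fwhm, HK amplitude, OSCC amplitude
  epi <- rbind(
    c(1650, 40, 1.00, 0.60),  # amide I
    c(1548, 32, 0.70, 0.42),  # amide II
    c(1450, 26, 0.30, 0.30),  # CH2/CH3 bending, class-neutral
    c(1310, 28, 0.30, 0.18),  # amide III
    c(1240, 30, 0.30, 0.50),  # asym PO2- stretch
    c(1154, 24, 0.12, 0.25),  # C-O carbohydrate
    c(1080, 28, 0.25, 0.45),  # sym PO2- stretch
    c(1030, 26, 0.20, 0.40),  # glycogen C-O
    c(966, 22, 0.15, 0.30)    # DNA phosphodiester
  )
  w <- oed_mix
  tab <- data.frame(
    center = epi[, 1], fwhm = epi[, 2],
    HK = epi[, 3],
    OED_HKlike = w * epi[, 3] + (1 - w) * epi[, 4],
    OED_OSCClike = (1 - w) * epi[, 3] + w * epi[, 4],
    OSCC = epi[, 4],
    STROMA = 0
  )
  # red-shifted amide II shoulder sub-bands (dysplasia and carcinoma only)
  tab <- rbind(tab,
    data.frame(center = 1548 - amideII_redshift[["OED"]], fwhm = 26,
               HK = 0, OED_HKlike = 0.04, OED_OSCClike = 0.04, OSCC = 0,
               STROMA = 0),
    data.frame(center = 1548 - amideII_redshift[["OSCC"]], fwhm = 26,
               HK = 0, OED_HKlike = 0, OED_OSCClike = 0, OSCC = 0.06,
               STROMA = 0))
  # collagen-dominated stroma profile
  stroma <- rbind(
    c(1660, 40, 0.95), c(1552, 32, 0.55), c(1450, 26, 0.25),
    c(1338, 24, 0.35), c(1282, 24, 0.30), c(1204, 22, 0.28),
    c(1080, 28, 0.15), c(1030, 26, 0.12)
  )
  tab <- rbind(tab, data.frame(center = stroma[, 1], fwhm = stroma[, 2],
                               HK = 0, OED_HKlike = 0, OED_OSCClike = 0,
                               OSCC = 0, STROMA = stroma[, 3]))
  if (any(tab$center > 1700 & tab$center < 1750)) {
    stop("band table places a band in the absent lipid region 1750-1700")
  }
  rownames(tab) <- NULL
  tab
}

#' Distortion configuration for the synthetic generator
#'
#' Describes the physical artifacts the preprocessing chain must undo:
#' multiplicative scatter, smooth polynomial baseline drift and additive
#' noise (all applied in absorbance space before conversion to
#' transmission), plus a fraction of extreme outlier pixels.
#'
#' @param scatter_scale_range Interval of the multiplicative scatter
#'   factor, strictly positive.
#' @param baseline_poly_order Polynomial order of the random baseline.
#' @param baseline_coeff_sd Standard deviations of the baseline
#'   coefficients, length `baseline_poly_order + 1`.
#' @param noise_sd Additive noise SD in absorbance units.
#' @param outlier_pixel_fraction Probability that a pixel is generated as
#'   an outlier, in `[0, 1)`.
#' @param outlier_multiplier Factor applied to baseline coefficients and
#'   noise of outlier pixels.
#' @return A `distortion_config` list.
#' @export
distortion_config <- function(scatter_scale_range = c(0.85, 1.15),
                              baseline_poly_order = 2,
                              baseline_coeff_sd = c(0.04, 0.02, 0.01),
                              noise_sd = 0.004,
                              outlier_pixel_fraction = 0.02,
                              outlier_multiplier = 10) {
  stopifnot(length(scatter_scale_range) == 2, all(scatter_scale_range > 0),
            scatter_scale_range[1] <= scatter_scale_range[2],
            baseline_poly_order >= 0,
            length(baseline_coeff_sd) == baseline_poly_order + 1,
            all(baseline_coeff_sd >= 0), noise_sd >= 0,
            outlier_pixel_fraction >= 0, outlier_pixel_fraction < 1,
            outlier_multiplier >= 1)
  structure(list(scatter_scale_range = as.numeric(scatter_scale_range),
                 baseline_poly_order = as.integer(baseline_poly_order),
                 baseline_coeff_sd = as.numeric(baseline_coeff_sd),
                 noise_sd = noise_sd,
                 outlier_pixel_fraction = outlier_pixel_fraction,
                 outlier_multiplier = outlier_multiplier),
            class = "distortion_config")
}

#' Distortion-free configuration (no scatter, baseline, noise or outliers)
#' @return A `distortion_config` with every distortion switched off.
#' @export
zero_distortion <- function() {
  distortion_config(scatter_scale_range = c(1, 1), baseline_poly_order = 0,
                    baseline_coeff_sd = 0, noise_sd = 0,
                    outlier_pixel_fraction = 0)
}

#' Cohort scenario: the study design the generator emulates
#'
#' The default mirrors the study design: 12 hyperkeratosis (H), 11
#' carcinoma (C) and 11 dysplasia (D) samples, the dysplasia samples
#' carrying latent grades in the order D-01..D-11 =
#' OSCClike, HKlike, HKlike, OSCClike, HKlike, OSCClike, HKlike,
#' OSCClike, HKlike, borderline, HKlike (6 HK-like, 4 OSCC-like, 1
#' borderline).
#'
#' @param n_hk,n_oscc Sample counts per class.
#' @param oed_ground_truth Character vector of latent dysplasia grades,
#'   each `"HKlike"`, `"OSCClike"` or `"borderline"`.
#' @param areas_per_sample Imaging areas acquired per sample (>= 2).
#' @param stroma_fraction Fraction of stroma pixels per area, in `[0, 1)`.
#' @param seed Integer seed for the whole cohort.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_hk = 12, n_oscc = 11,
                            oed_ground_truth = c("OSCClike", "HKlike", "HKlike",
                                                 "OSCClike", "HKlike", "OSCClike",
                                                 "HKlike", "OSCClike", "HKlike",
                                                 "borderline", "HKlike"),
                            areas_per_sample = 3,
                            stroma_fraction = 0.2,
                            seed = 42) {
  stopifnot(n_hk >= 0, n_oscc >= 0, areas_per_sample >= 2,
            stroma_fraction >= 0, stroma_fraction < 1,
            all(oed_ground_truth %in% c("HKlike", "OSCClike", "borderline")))
  structure(list(n_hk = as.integer(n_hk), n_oscc = as.integer(n_oscc),
                 oed_ground_truth = as.character(oed_ground_truth),
                 areas_per_sample = as.integer(areas_per_sample),
                 stroma_fraction = stroma_fraction, seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Build a clean (distortion-free) class spectrum
#'
#' Sum of Gaussian bands evaluated on the grid for one tissue profile.
#'
#' @param class_label One of `"HK"`, `"OED_HKlike"`, `"OED_OSCClike"`,
#'   `"OSCC"`, `"STROMA"`.
#' @param band_table Data frame as returned by [default_band_table()].
#' @param grid Wavenumber grid (cm^-1).
#' @return Numeric absorbance spectrum on `grid`, nonnegative.
#' @export
build_clean_spectrum <- function(class_label, band_table = default_band_table(),
                                 grid = default_grid()) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% synthetic_classes) {
    stop("unknown class label: ", paste(class_label, collapse = ","),
         " (expected one of ", paste(synthetic_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  s <- numeric(length(grid))
  if (nrow(band_table) == 0L) return(s)
  amp <- band_table[[class_label]]
  for (i in seq_len(nrow(band_table))) {
    if (amp[i] == 0) next
    sigma2 <- band_table$fwhm[i]^2 / (8 * log(2))
    s <- s + amp[i] * exp(-(grid - band_table$center[i])^2 / (2 * sigma2))
  }
  s
}

# vectorized distortion of a stack of clean absorbance rows; draws from the
# current RNG stream. Returns transmission matrix clipped to [1e-6, 1].
distort_matrix <- function(clean, cfg, outlier = rep(FALSE, nrow(clean)),
                           grid) {
  n <- nrow(clean); p <- ncol(clean)
  mult <- ifelse(outlier, cfg$outlier_multiplier, 1)
  scale <- runif(n, cfg$scatter_scale_range[1], cfg$scatter_scale_range[2])
  z <- if (p > 1) 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1 else 0
  P <- outer(z, 0:cfg$baseline_poly_order, `^`)           # p x (ord+1)
  coef <- matrix(rnorm(n * (cfg$baseline_poly_order + 1)), nrow = n) *
    rep(cfg$baseline_coeff_sd, each = n) * mult
  baseline <- coef %*% t(P)
  noise <- matrix(rnorm(n * p, sd = 1), n, p) * cfg$noise_sd * mult
  a <- clean * scale + baseline + noise
  t_mat <- 10^(-a)
  t_mat[t_mat > 1] <- 1
  t_mat[t_mat < 1e-6] <- 1e-6
  t_mat
}

#' Distort a clean absorbance spectrum into a transmission spectrum
#'
#' Applies multiplicative scatter, a random polynomial baseline and
#' additive noise in absorbance space, then converts via T = 10^(-A).
#' T is clipped to `[1e-6, 1]` so the log stays defined downstream.
#' Draws from the current RNG stream: call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param clean Numeric absorbance spectrum.
#' @param cfg A [distortion_config()].
#' @param grid Wavenumber grid matching `clean`.
#' @param outlier Logical; apply the outlier multiplier.
#' @return Numeric transmission spectrum in `(0, 1]`.
#' @export
distort_to_transmission <- function(clean, cfg = distortion_config(),
                                    grid = default_grid(), outlier = FALSE) {
  stopifnot(length(clean) == length(grid))
  drop(distort_matrix(matrix(clean, nrow = 1L), cfg, outlier, grid))
}

#' Generate one 16 x 16 imaging area
#'
#' 256 pixel transmission spectra for one sample: epithelial pixels drawn
#' from `profile`, stroma pixels (at `scenario$stroma_fraction`) from the
#' stroma profile, and outlier pixels (at `cfg$outlier_pixel_fraction`)
#' with extreme baseline/noise. The per-pixel ground-truth tissue label
#' (`epithelium`, `stroma`, `outlier`) is carried in `meta$tissue`.
#'
#' @param sample_id,area_id Identifiers recorded in the metadata.
#' @param class_label Sample class `"H"`, `"D"` or `"C"`.
#' @param profile Band-table profile used for the epithelial pixels.
#' @param scenario A [cohort_scenario()].
#' @param cfg A [distortion_config()].
#' @param band_table,grid Band model and wavenumber grid.
#' @param npix_side Pixels per side of the square area (16).
#' @return A `spectrum_set` (mode `"transmission"`) of
#'   `npix_side^2` rows.
#' @export
generate_area <- function(sample_id, area_id, class_label, profile,
                          scenario = cohort_scenario(),
                          cfg = distortion_config(),
                          band_table = default_band_table(),
                          grid = default_grid(), npix_side = 16) {
  npix <- npix_side^2
  clean_epi <- build_clean_spectrum(profile, band_table, grid)
  clean_str <- build_clean_spectrum("STROMA", band_table, grid)
  n_stroma <- round(scenario$stroma_fraction * npix)
  tissue <- rep("epithelium", npix)
  if (n_stroma > 0) tissue[sample.int(npix, n_stroma)] <- "stroma"
  outlier <- runif(npix) < cfg$outlier_pixel_fraction
  clean <- matrix(clean_epi, npix, length(grid), byrow = TRUE)
  if (n_stroma > 0) clean[tissue == "stroma", ] <-
    matrix(clean_str, n_stroma, length(grid), byrow = TRUE)
  x <- distort_matrix(clean, cfg, outlier, grid)
  tissue[outlier] <- "outlier"
  meta <- data.frame(sample_id = sample_id, area_id = area_id,
                     class = class_label, role = "pixel", tissue = tissue,
                     stringsAsFactors = FALSE)
  spectrum_set(grid, x, meta, mode = "transmission")
}

#' Generate a full synthetic cohort
#'
#' One list of imaging areas per sample, with ground truth. Dysplasia
#' samples draw their epithelial pixels from the `OED_HKlike` or
#' `OED_OSCClike` profile according to the latent grade; a borderline
#' sample draws half its areas (rounded up) from the HK-like profile and
#' the rest from the OSCC-like profile. Seeded from `scenario$seed`
#' unless `seed` overrides it; same seed gives identical output.
#'
#' @param scenario A [cohort_scenario()].
#' @param cfg A [distortion_config()].
#' @param band_table,grid Band model and wavenumber grid.
#' @param seed Optional integer overriding `scenario$seed`.
#' @return A list with `areas` (list of per-area `spectrum_set`s),
#'   `samples` (data frame: `sample_id`, `class`, `latent_grade`),
#'   `scenario` and `cfg`.
#' @export
generate_cohort <- function(scenario = cohort_scenario(),
                            cfg = distortion_config(),
                            band_table = default_band_table(),
                            grid = default_grid(), seed = NULL) {
  set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
  n_oed <- length(scenario$oed_ground_truth)
  samples <- data.frame(
    sample_id = c(sprintf("H-%02d", seq_len(scenario$n_hk)),
                  sprintf("C-%02d", seq_len(scenario$n_oscc)),
                  sprintf("D-%02d", seq_len(n_oed))),
    class = c(rep("H", scenario$n_hk), rep("C", scenario$n_oscc),
              rep("D", n_oed)),
    latent_grade = c(rep(NA_character_, scenario$n_hk + scenario$n_oscc),
                     scenario$oed_ground_truth),
    stringsAsFactors = FALSE)
  k <- scenario$areas_per_sample
  areas <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    profiles <- switch(samples$class[i],
      H = rep("HK", k),
      C = rep("OSCC", k),
      D = switch(samples$latent_grade[i],
        HKlike = rep("OED_HKlike", k),
        OSCClike = rep("OED_OSCClike", k),
        borderline = c(rep("OED_HKlike", ceiling(k / 2)),
                       rep("OED_OSCClike", k - ceiling(k / 2)))))
    for (j in seq_len(k)) {
      aid <- sprintf("%s_a%02d", sid, j)
      areas[[aid]] <- generate_area(sid, aid, samples$class[i], profiles[j],
                                    scenario, cfg, band_table, grid)
    }
  }
  list(areas = areas, samples = samples, scenario = scenario, cfg = cfg)
}
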