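test_that("absorbance conversion is log10(1/T) with strict positivity", {
  s <- mk_set(matrix(c(1, 0.1, 0.01), 1), mode = "transmission")
  a <- transmittance_to_absorbance(s)
  expect_equal(drop(a$x), c(0, 1, 2))
  expect_identical(a$mode, "absorbance")
  bad <- mk_set(matrix(c(0.5, 0, 0.5), 1), mode = "transmission")
  expect_error(transmittance_to_absorbance(bad), "row 1, column 2")
  expect_error(transmittance_to_absorbance(a), "transmission")
})

test_that("fingerprint selection keeps exactly the in-region columns", {
  full <- mk_set(matrix(rnorm(2 * 1526), 2), grid = seq(4000, 950, by = -2))
  fp <- select_fingerprint(full, c(1800, 950))
  expect_true(all(fp$wavenumbers >= 950 & fp$wavenumbers <= 1800))
  expect_equal(ncol(fp$x), 426)
  # identity cases
  s <- rand_set(2, 426)
  expect_equal(select_fingerprint(s, c(1800, 950))$x, s$x)
  expect_equal(select_fingerprint(s, range(s$wavenumbers))$x, s$x)
})

test_that("Savitzky-Golay reproduces polynomials exactly, including edges", {
  g <- seq(1800, by = -2, length.out = 60)
  u <- seq_along(g)
  for (ord in c(2, 3)) {
    y <- 0.3 + 0.02 * u + 0.001 * u^2 + if (ord == 3) 1e-5 * u^3 else 0
    sm <- savgol(mk_set(y, g), window = 9, polyorder = ord, deriv_order = 0)
    expect_equal(drop(sm$x), y, tolerance = 1e-9)
  }
  # second derivative of a*x^2 (x = wavenumber) is constant 2a
  a <- 0.004
  y2 <- a * g^2
  d2 <- savgol(mk_set(y2, g), window = 7, polyorder = 3, deriv_order = 2)
  expect_equal(drop(d2$x), rep(2 * a, length(g)), tolerance = 1e-8)
  expect_identical(d2$mode, "derivative")
  expect_error(savgol(mk_set(y2[1:5], g[1:5]), window = 7), "window")
})

test_that("Savitzky-Golay matches the sliding polyfit oracle and signal::sgolayfilt", {
  set.seed(42)
  g <- seq(1800, by = -2, length.out = 120)
  h <- 2
  for (case in list(c(9, 2, 0), c(7, 3, 2), c(11, 4, 0))) {
    y <- rnorm(length(g))
    got <- drop(savgol(mk_set(y, g), case[1], case[2], case[3])$x)
    want <- oracle_savgol(y, h, case[1], case[2], case[3])
    interior <- !is.na(want)
    expect_equal(got[interior], want[interior], tolerance = 1e-10)
    if (requireNamespace("signal", quietly = TRUE)) {
      ref <- signal::sgolayfilt(y, p = case[2], n = case[1], m = case[3],
                                ts = h)
      expect_equal(got[interior], ref[interior], tolerance = 1e-8)
    }
  }
})

test_that("EMSC corrects offset/scale/background against its reference", {
  set.seed(7)
  g <- default_grid()
  ref <- build_clean_spectrum("HK", grid = g)
  # row identical to the reference is untouched
  same <- emsc(mk_set(ref, g), reference = ref)
  expect_equal(drop(same$x), ref, tolerance = 1e-10)
  # affine distortion is inverted exactly (normal-equations solution)
  distorted <- mk_set(2 * ref + 0.3, g)
  expect_equal(drop(emsc(distorted, reference = ref)$x), ref,
               tolerance = 1e-10)
  # scattered cohort: between-row variance strictly shrinks
  rows <- t(sapply(1:20, function(i)
    runif(1, 0.7, 1.4) * ref + runif(1, -0.2, 0.2) +
      rnorm(1, sd = 0.05) * seq(-1, 1, length.out = length(g))))
  scat <- mk_set(rows, g)
  corrected <- emsc(scat, reference = ref)
  expect_lt(mean(apply(corrected$x, 2, var)), mean(apply(scat$x, 2, var)))
  # near-zero scale row is flagged and passed through
  flat <- mk_set(rbind(ref, 0 * ref + 0.2), g)
  expect_warning(out <- emsc(flat, reference = ref), "near-zero")
  expect_equal(attr(out, "emsc_flagged"), 2L)
  expect_equal(out$x[2, ], 0 * ref + 0.2)
})

test_that("AWLS recovers known polynomial baselines under peaks", {
  g <- default_grid()
  zero <- awls_baseline(mk_set(rep(0, length(g)), g))
  expect_equal(drop(zero$x), rep(0, length(g)))
  # a pure quadratic is its own baseline: residual ~ 0
  z <- seq(-1, 1, length.out = length(g))
  quad <- 0.5 - 0.3 * z + 0.2 * z^2
  fit <- awls_baseline(mk_set(quad, g), poly_order = 2)
  expect_lt(max(abs(fit$x)), 1e-8)
  # Gaussian peaks on a known quadratic: recovered baseline within 2% of
  # its range in peak-free windows
  peaks <- build_clean_spectrum("HK", grid = g)
  y <- peaks + quad
  out <- awls_baseline(mk_set(y, g), poly_order = 2)
  bl <- drop(attr(out, "awls_baseline"))
  free <- peaks < 1e-3
  expect_true(any(free))
  expect_lt(max(abs(bl[free] - quad[free])), 0.02 * diff(range(quad)))
})

test_that("vector normalization is unit-norm, idempotent and scale-invariant", {
  s <- rand_set(4, 50, seed = 3)
  v <- vector_normalize(s)
  expect_equal(sqrt(rowSums(v$x^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(vector_normalize(v)$x, v$x, tolerance = 1e-12)
  s5 <- s; s5$x <- 5 * s5$x
  expect_equal(vector_normalize(s5)$x, v$x, tolerance = 1e-12)
  z <- s; z$x[2, ] <- 0
  expect_error(vector_normalize(z), "2")
  expect_equal(n_spectra(vector_normalize(z, on_zero = "drop")), 3)
})

test_that("the general chain preserves class band orderings and tracks mode", {
  sc <- cohort_scenario(n_hk = 1, n_oscc = 1, oed_ground_truth = character(0),
                        stroma_fraction = 0, areas_per_sample = 2, seed = 4)
  ch <- generate_cohort(sc, zero_distortion())
  pp <- lapply(ch$areas, preprocess_general)
  cls <- vapply(pp, function(s) s$meta$class[1], character(1))
  hk <- bind_spectra(pp[cls == "H"]); oscc <- bind_spectra(pp[cls == "C"])
  for (wn in c(1650, 1548)) expect_gt(band_mean(hk, wn), band_mean(oscc, wn))
  for (wn in c(1240, 1080, 1030)) {
    expect_lt(band_mean(hk, wn), band_mean(oscc, wn))
  }
  # derivative flag flips the mode and keeps unit norms
  dcfg <- preprocess_config(apply_derivative = TRUE)
  d <- preprocess_general(ch$areas[[1]], dcfg)
  expect_identical(d$mode, "derivative")
  expect_equal(sqrt(rowSums(d$x^2)), rep(1, n_spectra(d)), tolerance = 1e-12)
})

test_that("a permuted step order is rejected up front", {
  expect_error(preprocess_config(step_order = c("savgol", "absorbance",
                                                "fingerprint", "emsc", "awls",
                                                "vector_normalize")),
               "order-sensitive")
})

test_that("the scale/baseline/norm sub-chain contracts to an exact fixed point", {
  sc <- cohort_scenario(n_hk = 1, n_oscc = 0, oed_ground_truth = character(0),
                        stroma_fraction = 0, areas_per_sample = 2, seed = 6)
  ch <- generate_cohort(sc, mild_distortion())
  once <- preprocess_general(ch$areas[[1]])
  # re-applying EMSC (against its own mean), AWLS and normalization moves
  # each unit-norm row by under 1% -- the residual projection of noise
  # onto the refreshed EMSC basis -- and the result is an exact fixed
  # point: a third application changes nothing. Smoothing is excluded
  # because polynomial smoothing is not an idempotent operator.
  sub_chain <- function(s) vector_normalize(awls_baseline(emsc(s)))
  twice <- sub_chain(once)
  delta1 <- sqrt(rowSums((twice$x - once$x)^2))
  expect_lt(max(delta1), 0.01)
  thrice <- sub_chain(twice)
  delta2 <- sqrt(rowSums((thrice$x - twice$x)^2))
  expect_lt(max(delta2), 1e-12)
})
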