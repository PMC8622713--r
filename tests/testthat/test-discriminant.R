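test_that("PLS1 finds a rank-1 signal and reproduces perfectly separable labels", {
  n <- 20; p <- 15
  y_cls <- rep(c("H", "C"), each = n / 2)
  # X carries the class signal in column 7 only (rank-1 information)
  x <- matrix(1, n, p)
  x[, 7] <- ifelse(y_cls == "C", 1, 0)
  s <- mk_set(x, class = y_cls)
  m <- fit_plsda(s, n_lv = 1)
  expect_equal(which.max(abs(m$b)), 7)
  pr <- predict(m, s)
  expect_equal(pr$score, as.numeric(y_cls == "C"), tolerance = 1e-8)
  expect_identical(pr$class, y_cls)
})

test_that("the regression vector matches an independent NIPALS recursion", {
  set.seed(8)
  for (a in c(1, 3, 5)) {
    x <- matrix(rnorm(30 * 12), 30, 12)
    cls <- rep(c("H", "C"), 15)
    y <- as.numeric(cls == "C")
    m <- fit_plsda(mk_set(x, class = cls), n_lv = a)
    expect_equal(m$b, oracle_pls1_coef(x, y, a), tolerance = 1e-8)
  }
})

test_that("score vectors are mutually orthogonal and PLS saturates to least squares", {
  set.seed(9)
  n <- 12; p <- 15
  x <- matrix(rnorm(n * p), n, p)
  cls <- rep(c("H", "C"), 6)
  m <- fit_plsda(mk_set(x, class = cls), n_lv = 8)
  G <- crossprod(m$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # saturation: with n_lv = rows - 1 <= cols on full-rank X, the fit
  # reaches the interpolating least-squares solution
  msat <- fit_plsda(mk_set(x, class = cls), n_lv = n - 1)
  pr <- predict(msat, mk_set(x, class = cls))
  expect_equal(pr$score, as.numeric(cls == "C"), tolerance = 1e-6)
})

test_that("prediction enforces the contract: grid match, threshold, tie rule", {
  set.seed(10)
  x <- matrix(rnorm(20 * 8), 20, 8)
  cls <- rep(c("H", "C"), 10)
  s <- mk_set(x, class = cls)
  m <- fit_plsda(s, n_lv = 2)
  # permuted-grid input is rejected
  wrong <- spectrum_set(rev(s$wavenumbers) + 100, x, s$meta)
  expect_error(predict(m, wrong), "grid")
  # a score exactly at the threshold classifies as the positive class
  x0 <- matrix(m$x_mean, 1) + 0  # centered row scores exactly y_mean
  m2 <- m; m2$threshold <- m$y_mean
  expect_identical(predict(m2, x0)$class, "C")
  expect_equal(predict(m, x0)$side, m$y_mean - m$threshold)
})

test_that("single-class training sets and oversized LV counts are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_plsda(mk_set(x, class = rep("H", 10))), "single class")
  expect_error(fit_plsda(mk_set(x, class = rep(c("H", "C"), 5)), n_lv = 9),
               "exceeds")
})

test_that("LV selection picks the smallest count at minimal CV error", {
  # perfectly separable along one direction: 1 LV suffices
  reps <- clean_representatives(n_hk = 6, n_oscc = 6, noise_sd = 0.002,
                                seed = 11)
  folds <- venetian_blinds(reps$meta$sample_id, k = 4)
  sel <- select_n_lv(reps, folds = folds, max_lv = 6)
  expect_equal(length(sel$cv_error), 6)
  expect_equal(length(sel$cal_error), 6)
  expect_equal(sel$n_lv, 1)
  expect_equal(sel$cv_error[sel$n_lv], 0)
  # deterministic: same inputs give the same curves
  sel2 <- select_n_lv(reps, folds = folds, max_lv = 6)
  expect_identical(sel, sel2)
})

test_that("explained X variance matches the reconstruction-norm oracle", {
  set.seed(12)
  x <- matrix(rnorm(18 * 9), 18, 9)
  cls <- rep(c("H", "C"), 9)
  m <- fit_plsda(mk_set(x, class = cls), n_lv = 4)
  xc <- scale(x, center = TRUE, scale = FALSE)
  tot <- sum(xc^2)
  for (a in 1:4) {
    rec <- tcrossprod(m$x_scores[, a], m$x_loadings[, a])
    expect_equal(m$explained_x_variance[a], 100 * sum(rec^2) / tot,
                 tolerance = 1e-8)
  }
  expect_lte(sum(m$explained_x_variance), 100 + 1e-8)
  # rank-1 X: one LV explains everything
  r1 <- outer(as.numeric(cls == "C") + rnorm(18, sd = 1e-8), rnorm(9))
  m1 <- fit_plsda(mk_set(r1, class = cls), n_lv = 1)
  expect_equal(m1$explained_x_variance[1], 100, tolerance = 1e-4)
})

test_that("feature bands are signed local extrema above the prominence cut", {
  g <- default_grid()
  gauss <- function(c0, fwhm) exp(-(g - c0)^2 / (2 * (fwhm / 2.355)^2))
  fake <- fit_plsda(mk_set(matrix(rnorm(8 * length(g)), 8), g,
                           class = rep(c("H", "C"), 4)), n_lv = 2)
  fake$x_loadings[, 1] <- gauss(1548, 30) - 0.8 * gauss(1482, 30)
  fake$x_loadings[, 2] <- 0
  bands <- extract_feature_bands(fake, 1:2, prominence_fraction = 0.2)
  expect_equal(nrow(bands), 2)
  expect_equal(bands$wavenumber, c(1548, 1482))
  expect_equal(bands$sign, c("+", "-"))
  expect_true(all(bands$lv_index == 1))   # zero loading yields nothing
  # single positive band
  fake$x_loadings[, 1] <- gauss(1650, 40)
  one <- extract_feature_bands(fake, 1, prominence_fraction = 0.2)
  expect_equal(one$wavenumber, 1650)
  expect_equal(one$sign, "+")
})

test_that("comparators honor the shared contract on a separable fixture", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("xgboost")
  reps <- clean_representatives(n_hk = 5, n_oscc = 5, noise_sd = 0.002,
                                seed = 13)
  folds <- venetian_blinds(reps$meta$sample_id, k = 5)
  for (kind in c("svm_rbf", "gradient_boosted_trees")) {
    cmp <- fit_comparator(comparator_spec(kind), reps, folds = folds,
                          seed = 99)
    pr <- predict(cmp, reps)
    expect_identical(pr$class, reps$meta$class)
    expect_true(all(pr$score >= 0 & pr$score <= 1))
    # same seed, same tuned hyperparameters
    cmp2 <- fit_comparator(comparator_spec(kind), reps, folds = folds,
                           seed = 99)
    expect_identical(cmp$hyper, cmp2$hyper)
  }
  expect_error(comparator_spec("nearest_centroid"))
})

test_that("band annotation joins extracted bands to the literature lookup", {
  ann <- band_annotations()
  expect_equal(nrow(ann), 12)
  bands <- data.frame(wavenumber = c(1652, 1240, 1999), sign = "+",
                      lv_index = 1, loading_value = 1)
  out <- annotate_bands(bands)
  expect_match(out$assignment[1], "Amide I")
  expect_match(out$assignment[2], "phosphodiester")
  expect_true(is.na(out$assignment[3]))
})
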