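test_that("PCA matches the covariance eigendecomposition oracle", {
  s <- rand_set(40, 25, seed = 10)
  m <- fit_pca(s, n_components = 5)
  o <- oracle_pca(s$x, 5)
  expect_equal(m$eigenvalues[1:5], o$eigenvalues, tolerance = 1e-8)
  for (j in 1:5) {
    sgn <- sign(sum(m$loadings[, j] * o$loadings[, j]))
    expect_equal(m$loadings[, j], sgn * o$loadings[, j], tolerance = 1e-8)
    expect_equal(m$scores[, j], sgn * o$scores[, j], tolerance = 1e-8)
  }
})

test_that("PCA handles rank-1 data and reconstructs completely", {
  v <- rnorm(30)
  x <- outer(c(1, 2, 3, 5, 8), v)
  m1 <- fit_pca(mk_set(x))
  expect_equal(m1$n_components, 1)
  expect_equal(m1$explained_variance[1], 100, tolerance = 1e-8)
  s <- rand_set(12, 8, seed = 2)
  mfull <- fit_pca(s, n_components = 8)
  rec <- tcrossprod(mfull$scores, mfull$loadings) +
    matrix(mfull$mean, 12, 8, byrow = TRUE)
  expect_equal(rec, s$x, tolerance = 1e-10)
  expect_error(fit_pca(s, n_components = 20), "exceeds")
})

test_that("T2 and Q match their brute-force formulas", {
  s <- rand_set(60, 20, seed = 4)
  k <- 4
  m <- fit_pca(s, n_components = k)
  rep <- t2_q(m, s)
  o <- oracle_pca(s$x, k)
  xc <- scale(s$x, center = TRUE, scale = FALSE)
  sc <- xc %*% o$loadings
  t2 <- rowSums(sweep(sc^2, 2, o$eigenvalues, "/"))
  q <- rowSums((xc - sc %*% t(o$loadings))^2)
  t2_lim <- k * 59 / (60 - k) * qf(0.95, k, 60 - k)
  expect_equal(rep$reduced_t2, t2 / t2_lim, tolerance = 1e-8)
  expect_equal(rep$reduced_q * attr(rep, "q_limit"), q, tolerance = 1e-8)
  # a row at the training mean has T2 = 0; a row in the loading span has Q ~ 0
  at_mean <- matrix(m$mean, 1)
  expect_equal(t2_q(m, at_mean)$reduced_t2, 0)
  in_span <- at_mean + matrix(m$loadings[, 1], 1) * 3
  expect_lt(t2_q(m, in_span)$reduced_q, 1e-10)
})

test_that("outlier removal has power against injected pixels and controls FPR", {
  # single-fixture check here; replicate-level power is in the acceptance suite
  set.seed(21)
  sc <- cohort_scenario(stroma_fraction = 0)
  cfg <- distortion_config(outlier_pixel_fraction = 0.05)
  area <- generate_area("H-01", "a1", "H", "HK", sc, cfg)
  pre <- preprocess_general(area, on_zero = "drop")
  res <- remove_outliers(pre)
  truth <- pre$meta$tissue == "outlier"
  flagged <- res$report$is_outlier
  expect_gte(sum(flagged & truth) / sum(truth), 0.9)
  expect_lte(sum(flagged & !truth) / sum(!truth), 0.05)
  # tau = Inf disables removal
  expect_equal(n_spectra(remove_outliers(pre, tau_t = Inf, tau_q = Inf)$set),
               n_spectra(pre))
})

test_that("HCA separates tissue profiles and has n-1 merges", {
  set.seed(31)
  sc <- cohort_scenario(stroma_fraction = 0.3)
  area <- generate_area("H-01", "a1", "H", "HK", sc, mild_distortion())
  pre <- preprocess_general(area)
  tree <- hca(pre)
  expect_equal(nrow(tree$merge), n_spectra(pre) - 1)
  cl <- cut_k(tree, 2)
  truth <- pre$meta$tissue == "stroma"
  agree <- max(mean((cl == 1) == truth), mean((cl == 2) == truth))
  expect_gte(agree, 0.95)
  # identical rows merge at height zero
  same <- mk_set(matrix(1, 5, 10))
  expect_equal(hca(same)$height, rep(0, 4), tolerance = 1e-12)
})

test_that("epithelium selection keeps the majority cluster, or everything when homogeneous", {
  set.seed(32)
  sc <- cohort_scenario(stroma_fraction = 0.3)
  area <- generate_area("H-01", "a1", "H", "HK", sc, mild_distortion())
  pre <- preprocess_general(area)
  sel <- select_epithelium(pre)
  expect_equal(n_spectra(sel), sum(pre$meta$tissue == "epithelium"),
               tolerance = 0.02)
  expect_gte(mean(sel$meta$tissue == "epithelium"), 0.98)
  # minority override returns the other cluster
  sel_min <- select_epithelium(pre, designate = "minority")
  expect_equal(n_spectra(sel_min) + n_spectra(sel), n_spectra(pre))
  # homogeneous area: no split, all rows returned
  set.seed(33)
  area0 <- generate_area("H-01", "a1", "H", "HK",
                         cohort_scenario(stroma_fraction = 0),
                         mild_distortion())
  pre0 <- preprocess_general(area0)
  expect_equal(n_spectra(select_epithelium(pre0)), n_spectra(pre0))
})

test_that("representative spectra are exact column means with carried metadata", {
  s <- rand_set(256, 30, seed = 5)
  s$meta$sample_id <- "H-07"; s$meta$area_id <- "H-07_a02"; s$meta$class <- "H"
  r <- representative_spectrum(s)
  expect_equal(drop(r$x), colMeans(s$x), tolerance = 1e-12)
  expect_identical(r$meta$role, "representative")
  expect_identical(r$meta$area_id, "H-07_a02")
  one <- subset_rows(s, 3)
  expect_equal(drop(representative_spectrum(one)$x), s$x[3, ])
  two <- subset_rows(s, 1:2)
  expect_equal(drop(representative_spectrum(two)$x), (s$x[1, ] + s$x[2, ]) / 2)
})

test_that("two representatives per sample are the maximally distant pair", {
  g <- seq(1800, by = -2, length.out = 10)
  base <- rep(0, 10)
  # three areas at mutual distances 1, 2, 3: the distance-3 pair wins
  x <- rbind(base, base + c(1, rep(0, 9)), base - c(2, rep(0, 9)))
  meta <- data.frame(sample_id = "D-01", area_id = c("a1", "a2", "a3"),
                     class = "D", role = "representative")
  reps <- spectrum_set(g, x, meta)
  sel <- select_two_per_sample(reps)
  expect_equal(sort(sel$meta$area_id), c("a2", "a3"))
  # exactly two areas: both returned
  two <- subset_rows(reps, 1:2)
  expect_equal(n_spectra(select_two_per_sample(two)), 2)
  # single-area sample errors with advice
  expect_error(select_two_per_sample(subset_rows(reps, 1)), "at least 2")
})

test_that("class averages count the expected representatives", {
  set.seed(6)
  g <- seq(1800, by = -2, length.out = 8)
  n <- c(H = 24, D = 22, C = 22)
  x <- matrix(rnorm(sum(n) * 8), sum(n), 8)
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(sum(n))),
                     class = rep(names(n), n))
  reps <- spectrum_set(g, x, meta)
  for (cls in names(n)) {
    avg <- class_average(reps, cls)
    expect_equal(attr(avg, "n_averaged"), unname(n[cls]))
    expect_equal(drop(avg$x), colMeans(x[meta$class == cls, ]),
                 tolerance = 1e-12)
  }
  single <- subset_rows(reps, 1)
  expect_equal(drop(class_average(single, "H")$x), x[1, ])
  expect_error(class_average(reps, "Z"), "no rows")
})

test_that("QC artifacts persist as CSV and JSON merge lists", {
  s <- rand_set(20, 8, seed = 44)
  rep <- t2_q(fit_pca(s, n_components = 2), s)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_outlier_report(rep, p1)
  back <- utils::read.csv(p1)
  expect_equal(back$reduced_t2, rep$reduced_t2, tolerance = 1e-12)
  expect_equal(unique(back$tau_t), 3)
  tree <- hca(s)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cluster_tree(tree, p2)
  j <- jsonlite::read_json(p2, simplifyVector = FALSE)
  expect_equal(unlist(j$height), tree$height, tolerance = 1e-12)
  expect_equal(length(j$merge), 19)
  expect_equal(unlist(j$merge[[19]]), tree$merge[19, ])
})
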