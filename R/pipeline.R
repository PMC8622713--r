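#' Pipeline run configuration
#'
#' @param scenario A [cohort_scenario()].
#' @param distortion A [distortion_config()].
#' @param preprocess A [preprocess_config()]; the derivative step is
#'   applied to the representative spectra before modeling when
#'   `apply_derivative` is set (the default here).
#' @param max_lv Largest LV count considered when selecting the model.
#' @param cv_k Number of venetian-blinds folds.
#' @param threshold PLS-DA decision threshold.
#' @param delta Borderline half-width for dysplasia grading.
#' @param tau_t,tau_q Reduced T2 / Q outlier thresholds.
#' @param comparators Character vector of comparator kinds to evaluate
#'   alongside the PLS-DA model (may be empty).
#' @param seed Master seed; each stage derives its own stream from it.
#' @param write_cubes Also persist every generated area as an ENVI cube.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = cohort_scenario(),
                       distortion = distortion_config(),
                       preprocess = preprocess_config(apply_derivative = TRUE),
                       max_lv = 10, cv_k = 10, threshold = 0.5, delta = 0,
                       tau_t = 3, tau_q = 3,
                       comparators = character(0),
                       seed = scenario$seed, write_cubes = FALSE) {
  if (is.null(scenario)) stop("config validation: scenario is missing",
                              call. = FALSE)
  stopifnot(inherits(scenario, "cohort_scenario"),
            inherits(distortion, "distortion_config"),
            inherits(preprocess, "preprocess_config"),
            max_lv >= 1, cv_k >= 2, delta >= 0)
  structure(list(scenario = scenario, distortion = distortion,
                 preprocess = preprocess, max_lv = as.integer(max_lv),
                 cv_k = as.integer(cv_k), threshold = threshold,
                 delta = delta, tau_t = tau_t, tau_q = tau_q,
                 comparators = comparators, seed = as.integer(seed),
                 write_cubes = isTRUE(write_cubes)),
            class = "run_config")
}

# deterministic per-stage seed fork (kept below 2^31)
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + stage_index * 9973) %% 2147483647)
}

#' Derive representative spectra from a generated cohort
#'
#' Per area: general (non-derivative) preprocessing, reduced-T2/Q
#' outlier removal, HCA epithelium selection, then the column mean as
#' the area's representative spectrum; per sample, the two most distant
#' representatives are retained.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config A [run_config()].
#' @return List with `representatives` (2 rows per sample),
#'   `all_representatives` (one per area), and `qc_log` (per-area data
#'   frame of pixel counts in/out).
#' @export
cohort_representatives <- function(cohort, config = run_config()) {
  pp_cfg <- config$preprocess
  pp_cfg$apply_derivative <- FALSE
  reps <- list(); qc <- list()
  for (aid in names(cohort$areas)) {
    area <- cohort$areas[[aid]]
    pre <- preprocess_general(area, pp_cfg, on_zero = "drop")
    qcres <- remove_outliers(pre, tau_t = config$tau_t, tau_q = config$tau_q)
    epi <- select_epithelium(qcres$set)
    reps[[aid]] <- representative_spectrum(epi)
    qc[[aid]] <- data.frame(area_id = aid, n_pixels = n_spectra(area),
                            n_after_qc = n_spectra(qcres$set),
                            n_epithelium = n_spectra(epi))
  }
  all_reps <- bind_spectra(reps)
  list(representatives = select_two_per_sample(all_reps),
       all_representatives = all_reps,
       qc_log = do.call(rbind, qc))
}

#' Run the full pipeline: simulate, preprocess, QC, train, evaluate,
#' stratify
#'
#' Executes the stages in order on a synthetic cohort and persists every
#' stage output under `out_dir`: the 2-per-sample representative spectra
#' (CSV), the PLS-DA model (JSON), the cross-validation report (JSON),
#' the feature-band table (CSV), the dysplasia stratification table
#' (CSV + JSON), the QC log (CSV) and the resolved configuration
#' (JSON). Identical config + seed gives identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param verbose Emit one structured log line per stage (row counts in
#'   and out).
#' @return Invisibly, a list with `representatives`, `train` (the
#'   derivative-mode training set), `model`, `lv_selection`, `cv`,
#'   `stratification`, `bands`, `comparators`, `qc_log`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(...) if (verbose) message("[ftirstrat] ", ...)
  # stage 1: simulate
  cohort <- generate_cohort(config$scenario, config$distortion,
                            seed = stage_seed(config$seed, 1L))
  log_line("simulate: ", length(cohort$areas), " areas, ",
           nrow(cohort$samples), " samples")
  # stages 2-3: preprocess + QC -> representatives
  set.seed(stage_seed(config$seed, 2L))
  repres <- cohort_representatives(cohort, config)
  reps <- repres$representatives
  log_line("preprocess+qc: ", sum(repres$qc_log$n_pixels), " pixels in, ",
           sum(repres$qc_log$n_epithelium), " epithelial kept, ",
           n_spectra(reps), " representatives selected")
  # stage 4: model input (second derivative by default), HK/OSCC training
  model_set <- if (config$preprocess$apply_derivative) {
    vector_normalize(savgol(reps, config$preprocess$derivative_window,
                            config$preprocess$derivative_polyorder, 2))
  } else reps
  is_train <- model_set$meta$class %in% c("H", "C")
  train <- subset_rows(model_set, is_train)
  folds <- venetian_blinds(train$meta$sample_id, config$cv_k)
  set.seed(stage_seed(config$seed, 3L))
  sel <- select_n_lv(train, folds = folds, max_lv = config$max_lv,
                     threshold = config$threshold)
  model <- fit_plsda(train, n_lv = sel$n_lv, threshold = config$threshold)
  cv <- cross_validate(function(s, l) fit_plsda(s, l, n_lv = sel$n_lv,
                                                threshold = config$threshold),
                       train, folds = folds)
  comparators <- list()
  for (kind in config$comparators) {
    set.seed(stage_seed(config$seed, 4L))
    cmp <- fit_comparator(comparator_spec(kind), train, folds = folds,
                          threshold = config$threshold,
                          seed = stage_seed(config$seed, 4L))
    cmp_cv <- cross_validate(function(s, l) {
      fit_comparator_fixed(kind, s, l, hyper = cmp$hyper,
                           threshold = config$threshold,
                           seed = stage_seed(config$seed, 4L))
    }, train, folds = folds)
    comparators[[kind]] <- list(model = cmp, cv = cmp_cv)
  }
  log_line("train+evaluate: ", n_spectra(train), " training spectra, n_lv=",
           model$n_lv, ", sens=", round(cv$sensitivity, 3), ", spec=",
           round(cv$specificity, 3), ", auc=", round(cv$auc, 4))
  bands <- extract_feature_bands(model, seq_len(min(2, model$n_lv)))
  # stage 5: stratify dysplasia samples
  oed <- subset_rows(model_set, model_set$meta$class == "D")
  strat <- if (n_spectra(oed)) stratify_oed(model, oed, config$delta) else NULL
  if (!is.null(strat)) {
    log_line("stratify: ", paste(names(attr(strat, "counts")),
                                 attr(strat, "counts"), sep = "=",
                                 collapse = " "))
  }
  out <- list(representatives = reps, train = train, model = model,
              lv_selection = sel, cv = cv, stratification = strat,
              bands = bands, comparators = comparators,
              qc_log = repres$qc_log, samples = cohort$samples,
              out_dir = out_dir)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, cohort, config, out_dir)
  invisible(out)
}

write_pipeline_artifacts <- function(out, cohort, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_spectra(out$representatives,
                    file.path(out_dir, "representatives.csv"))
  utils::write.csv(out$qc_log, file.path(out_dir, "qc_log.csv"),
                   row.names = FALSE)
  m <- out$model
  jsonlite::write_json(
    list(n_lv = m$n_lv, threshold = m$threshold,
         wavenumbers = m$wavenumbers, b = m$b, x_mean = m$x_mean,
         y_mean = m$y_mean, weights = m$weights, x_loadings = m$x_loadings,
         y_loadings = m$y_loadings,
         explained_x_variance = m$explained_x_variance,
         class_coding = as.list(m$class_coding)),
    file.path(out_dir, "model.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(confusion = out$cv$confusion[c("tp", "fp", "tn", "fn")],
         sensitivity = out$cv$sensitivity, specificity = out$cv$specificity,
         auc = out$cv$auc, folds = out$cv$folds,
         scores = out$cv$scores, cv_error = out$lv_selection$cv_error,
         cal_error = out$lv_selection$cal_error, n_lv = out$lv_selection$n_lv),
    file.path(out_dir, "cv_report.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(out$bands, file.path(out_dir, "feature_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(out$cv$roc$points, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  if (!is.null(out$stratification)) {
    utils::write.csv(as.data.frame(out$stratification),
                     file.path(out_dir, "stratification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(table = as.data.frame(out$stratification),
           counts = as.list(attr(out$stratification, "counts"))),
      file.path(out_dir, "stratification.json"), digits = NA,
      auto_unbox = TRUE)
  }
  cfg_json <- list(seed = config$seed, scenario = unclass(config$scenario),
                   distortion = unclass(config$distortion),
                   preprocess = unclass(config$preprocess),
                   max_lv = config$max_lv, cv_k = config$cv_k,
                   threshold = config$threshold, delta = config$delta,
                   tau_t = config$tau_t, tau_q = config$tau_q)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  if (config$write_cubes) {
    cube_dir <- file.path(out_dir, "cubes")
    dir.create(cube_dir, showWarnings = FALSE)
    for (aid in names(cohort$areas)) {
      write_envi_cube(cohort$areas[[aid]], file.path(cube_dir, aid))
    }
  }
  invisible(out_dir)
}
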