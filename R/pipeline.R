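#' Pipeline run configuration
#'
#' Bundles the simulation, extraction, selection and classification settings.
#' Two presets: `"paper"` pins the full study conditions (110/106 subjects,
#' 90 parcels, 240 volumes at TR = 2 s, K = 6 states, window 40 / overlap
#' 0.975, 3 x 3 gamma-omega grid, 5 folds, 5,000 permutations, voxel mode);
#' `"desk"` is a reduced configuration (20/20 subjects, 20 parcels, node
#' mode, 200 permutations) sized for routine reruns on one CPU.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed; every stage derives its own from it.
#' @param ... overrides for any field (e.g. `n_perm`, `mode`, `sim` args).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("desk", "paper"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(sim = list(n_patients = 110L, n_controls = 106L, n_parcels = 90L,
                    n_volumes = 240L, tr_seconds = 2, n_states = 6L),
         mode = "voxel", n_drop = 10L, low_hz = 0.01, high_hz = 0.1,
         window = 40L, overlap = 0.975,
         gammas = c(0.9, 1, 1.1), omegas = c(0.5, 0.75, 1),
         K = 6L, hmm_restarts = 3L, ml_restarts = 3L,
         strategies = c("spearman", "lasso", "t_lasso"),
         kernels = c("linear", "polynomial", "rbf", "sigmoid"),
         n_folds = 5L, n_perm = 5000L,
         perm_strategy = "spearman", perm_kernels = c("rbf", "sigmoid"))
  } else {
    list(sim = list(n_patients = 20L, n_controls = 20L, n_parcels = 20L,
                    n_volumes = 240L, tr_seconds = 2, n_states = 6L),
         mode = "node", n_drop = 10L, low_hz = 0.01, high_hz = 0.1,
         window = 40L, overlap = 0.975,
         gammas = c(0.9, 1, 1.1), omegas = c(0.5, 0.75, 1),
         K = 6L, hmm_restarts = 2L, ml_restarts = 3L,
         strategies = c("spearman", "lasso", "t_lasso"),
         kernels = c("linear", "polynomial", "rbf", "sigmoid"),
         n_folds = 5L, n_perm = 200L,
         perm_strategy = "spearman", perm_kernels = c("rbf", "sigmoid"))
  }
  over <- list(...)
  if ("sim" %in% names(over)) {
    base$sim[names(over$sim)] <- over$sim
    over$sim <- NULL
  }
  base[names(over)] <- over
  base$preset <- preset
  base$seed <- as.integer(seed)
  structure(base, class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate (or ingest) a cohort, preprocess, extract static and dynamic
#' features, assemble the feature table, run every selection strategy with
#' every SVM kernel under stratified cross-validation, and (optionally)
#' permutation-test the configured strategy/kernels. Deterministic under the
#' configured seed.
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optional pre-built `synthetic_cohort` (must match the config
#'   mode); simulated from `cfg$sim` otherwise.
#' @param run_permutations run the label-permutation tests (can dominate the
#'   run time).
#' @return `pipeline_result`: list with `features` (feature_table),
#'   `metrics` (strategy x kernel summary data.frame), `cv` (full
#'   `cv_metrics` per strategy), `permutations`, `hmm`, `cohort_truth`,
#'   `timing` (seconds per stage), `cfg`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         run_permutations = TRUE) {
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.null(cohort)) {
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg, volumes = identical(cfg$mode, "voxel"))
  }
  timing["simulate"] <- tic() - t0

  t0 <- tic()
  tr <- cohort$cfg$tr_seconds
  subjects <- cohort$manifest$subject
  pp <- lapply(cohort$node_series, preprocess_series, n_drop = cfg$n_drop,
               low_hz = cfg$low_hz, high_hz = cfg$high_hz, tr_seconds = tr)
  filtered <- lapply(pp, function(p) p$filtered$data)
  timing["preprocess"] <- tic() - t0

  t0 <- tic()
  static <- if (identical(cfg$mode, "voxel")) {
    if (is.null(cohort$volumes))
      stop("voxel mode needs rendered volumes and an atlas in the cohort")
    lapply(cohort$volumes, static_features_voxel, atlas = cohort$atlas,
           tr_seconds = tr, n_drop = cfg$n_drop)
  } else {
    lapply(cohort$node_series, static_features_node, tr_seconds = tr,
           n_drop = cfg$n_drop)
  }
  timing["static"] <- tic() - t0

  t0 <- tic()
  nf <- lapply(seq_along(filtered), function(i)
    flexibility_grid(filtered[[i]], cfg$gammas, cfg$omegas,
                     window = cfg$window, overlap = cfg$overlap,
                     seed = cfg$seed + 13L * i, restarts = cfg$ml_restarts))
  names(nf) <- subjects
  timing["multilayer"] <- tic() - t0

  t0 <- tic()
  hmm <- hmm_dynamics(filtered, K = cfg$K, seed = cfg$seed + 101L,
                      restarts = cfg$hmm_restarts)
  timing["hmm"] <- tic() - t0

  t0 <- tic()
  ft <- assemble_features(static = static, nf = nf, hmm = hmm$features,
                          manifest = cohort$manifest)
  timing["assemble"] <- tic() - t0

  t0 <- tic()
  cv <- lapply(cfg$strategies, function(s)
    run_cv(ft, s, kernels = cfg$kernels, n_folds = cfg$n_folds,
           seed = cfg$seed + 211L))
  names(cv) <- cfg$strategies
  metrics <- do.call(rbind, lapply(cv, function(m) m$summary))
  rownames(metrics) <- NULL
  timing["classify"] <- tic() - t0

  perms <- NULL
  if (run_permutations && cfg$n_perm > 0) {
    t0 <- tic()
    perms <- lapply(cfg$perm_kernels, function(k)
      permutation_test(ft, cfg$perm_strategy, k, n_folds = cfg$n_folds,
                       n_perm = cfg$n_perm, seed = cfg$seed + 307L,
                       observed = cv[[cfg$perm_strategy]]))
    names(perms) <- cfg$perm_kernels
    timing["permutations"] <- tic() - t0
  }

  structure(list(features = ft, metrics = metrics, cv = cv,
                 permutations = perms, hmm = hmm,
                 cohort_truth = cohort$truth, timing = timing, cfg = cfg),
            class = "pipeline_result")
}

#' Human-readable strategy x kernel metrics table
#'
#' One row per feature-selection strategy and SVM kernel with the fold-mean
#' AUC, accuracy, sensitivity and specificity.
#'
#' @param result a `pipeline_result`, or a metrics data.frame.
#' @param digits rounding for display.
#' @return the formatted data.frame, invisibly (also printed).
#' @export
report_metrics <- function(result, digits = 4) {
  metrics <- if (inherits(result, "pipeline_result")) result$metrics else result
  if (is.null(metrics) || !nrow(metrics)) {
    warning("no metrics to report")
    out <- data.frame(strategy = character(0), kernel = character(0))
    print(out)
    return(invisible(out))
  }
  out <- data.frame(
    `Feature selection` = metrics$strategy,
    Classifier = metrics$kernel,
    AUC = round(metrics$auc, digits),
    Accuracy = round(metrics$accuracy, digits),
    Sensitivity = round(metrics$sensitivity, digits),
    Specificity = round(metrics$specificity, digits),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(out)
}

#' Write pipeline metrics (and permutation p-values) as JSON
#'
#' @param result a `pipeline_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  out <- list(metrics = result$metrics, timing = as.list(result$timing),
              seed = result$cfg$seed, preset = result$cfg$preset)
  if (!is.null(result$permutations))
    out$permutation_p <- lapply(result$permutations, function(p) p$p_value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
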