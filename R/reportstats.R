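#' Spearman correlation matrix between features and clinical covariates
#'
#' Tie-corrected Spearman rho (rank-then-Pearson) for every
#' (feature, clinical) pair with at least `min_pairs` complete observations,
#' with p-values from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant columns give masked (NA)
#' entries.
#'
#' @param feature_table Feature table.
#' @param clinical_columns Clinical covariate columns (default the simulated
#'   `hb`, `hbf`, `hba2`).
#' @param feature_columns Feature columns to correlate.
#' @param min_pairs Minimum number of complete pairs per cell.
#' @return List of matrices `rho` and `p` (features x clinical).
#' @export
spearman_matrix <- function(feature_table,
                            clinical_columns = c("hb", "hbf", "hba2"),
                            feature_columns = FEATURE_COLUMNS,
                            min_pairs = 5L) {
  feature_columns <- intersect(feature_columns, names(feature_table))
  clinical_columns <- intersect(clinical_columns, names(feature_table))
  if (!length(feature_columns) || !length(clinical_columns)) {
    stopf("no overlapping feature/clinical columns")
  }
  rho <- matrix(NA_real_, length(feature_columns), length(clinical_columns),
                dimnames = list(feature_columns, clinical_columns))
  p <- rho
  for (f in feature_columns) {
    for (cl in clinical_columns) {
      x <- feature_table[[f]]; y <- feature_table[[cl]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_pairs) next
      sc <- spearman_rho(x[ok], y[ok])
      rho[f, cl] <- sc$rho
      p[f, cl] <- sc$p
    }
  }
  list(rho = rho, p = p)
}

# rank-then-Pearson with midranks; large-sample t approximation for p
spearman_rho <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (is.na(r) || abs(r) >= 1 || n < 3) {
    return(list(rho = r, p = if (is.na(r)) NA_real_ else 0))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' PCA overview of the feature table
#'
#' Standardises the features (z-score, configurable) and runs a principal
#' component analysis; used as the unsupervised sanity view of class
#' separation.
#'
#' @param feature_table Feature table.
#' @param feature_columns Feature columns.
#' @param standardise Z-score the features first (default TRUE).
#' @return List with `scores` (samples x components),
#'   `variance_fraction` (sums to 1), `rotation`.
#' @export
pca_overview <- function(feature_table, feature_columns = FEATURE_COLUMNS,
                         standardise = TRUE) {
  feature_columns <- intersect(feature_columns, names(feature_table))
  X <- as.matrix(feature_table[, feature_columns, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stopf("PCA needs at least 3 complete samples")
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  fit <- stats::prcomp(X, center = TRUE, scale. = standardise)
  ev <- fit$sdev^2
  list(scores = fit$x,
       variance_fraction = ev / sum(ev),
       rotation = fit$rotation)
}

#' Binary grouping rules for the screening tasks
#'
#' Maps `(class_label, genotype_group)` to a binary label for one of the
#' three tasks: overall screening (thalassaemia vs control), the
#' beta-thalassaemia task (beta and alphabeta-compound samples vs
#' alpha-thalassaemia samples plus healthy controls), and the mirrored
#' alpha task.
#'
#' @param manifest Manifest or feature table with `class_label` and (for the
#'   genotype tasks) `genotype_group`.
#' @param task One of `thal_vs_control`, `beta_vs_nonbeta`,
#'   `alpha_vs_nonalpha`.
#' @return Character vector of `"positive"` / `"negative"`, one per row.
#' @export
#' @examples
#' m <- data.frame(sample_id = c("a", "b", "c"),
#'                 class_label = c("thalassaemia", "thalassaemia", "control"),
#'                 genotype_group = c("alphabeta", "alpha", "none"))
#' apply_grouping(m, "beta_vs_nonbeta")
apply_grouping <- function(manifest,
                           task = c("thal_vs_control", "beta_vs_nonbeta",
                                    "alpha_vs_nonalpha")) {
  task <- match.arg(task)
  if (task == "thal_vs_control") {
    return(ifelse(manifest$class_label == POSITIVE_CLASS,
                  "positive", "negative"))
  }
  if (!"genotype_group" %in% names(manifest)) {
    stopf("task '%s' needs a genotype_group column", task)
  }
  g <- manifest$genotype_group
  known <- c("alpha", "beta", "alphabeta", "none")
  bad <- setdiff(unique(g), known)
  if (length(bad)) {
    stopf("unmapped genotype_group value(s): %s", paste(bad, collapse = ", "))
  }
  pos_groups <- if (task == "beta_vs_nonbeta") c("beta", "alphabeta")
                else c("alpha", "alphabeta")
  ifelse(g %in% pos_groups, "positive", "negative")
}

#' Default pipeline configuration
#'
#' The demo study configuration: two cohorts with the default disease
#' profiles, acquisition artefacts switched on (baseline, mild noise, a
#' calibration drift typical of linear-mode runs), the paper-style
#' protocol parameters (2:1 split, top-5 selection for the screening task,
#' AUC > 0.85 selection for the genotype tasks, 3000 ppm matching), and the
#' screening task enabled.
#'
#' @param n_cohort1,n_cohort2 Named per-class sample counts.
#' @param methods Classifier families to run.
#' @param tasks Tasks to run (see [apply_grouping()]).
#' @return A named configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(n_cohort1 = c(control = 40, alpha_thal = 15,
                                                  beta_thal = 20,
                                                  alphabeta_compound = 5),
                                    n_cohort2 = c(control = 40, alpha_thal = 15,
                                                  beta_thal = 20,
                                                  alphabeta_compound = 5),
                                    methods = CLASSIFIER_METHODS,
                                    tasks = "thal_vs_control") {
  list(
    panel = list(),                       # defaults of globin_panel()
    profiles = list(beta_deficit = 0.5, alpha_deficit = 0.55,
                    between_sample_cv = 0.15),
    acquisition = list(noise_sd = 0.002, calibration_shift_ppm = 400,
                       sampling_step = 1),
    cohort1 = as.list(n_cohort1),
    cohort2 = as.list(n_cohort2),
    processing = list(smooth_window = 7, snip_iterations = 60,
                      snr_min = 3, min_spacing = 10,
                      tolerance_ppm = 3000, is_norm = "same_charge"),
    split = list(ratio = c(2, 1)),
    selection = list(thal_vs_control = list(top_k = 5),
                     beta_vs_nonbeta = list(auc_min = 0.85),
                     alpha_vs_nonalpha = list(auc_min = 0.85)),
    methods = methods,
    tasks = tasks,
    threshold = list(type = "fixed", value = 0.5)
  )
}

#' Run the whole screening study end to end
#'
#' Simulates (or ingests) two cohorts, processes every spectrum into the
#' ten-feature table, splits cohort 1 two-to-one into training and test sets,
#' and for each enabled task re-labels the samples, selects features on the
#' training data only, trains every requested classifier family and
#' evaluates it on the training, test and independent cohort-2 validation
#' tables. Fully reproducible from `(config, seed)`.
#'
#' @param config Configuration list (see [default_pipeline_config()]); a file
#'   path is accepted and read with [read_config()].
#' @param seed Master seed.
#' @param out_dir Optional output directory; when given, feature tables
#'   (CSV), per-task model reports (JSON) and a `run.json` provenance record
#'   are written there.
#' @param spectra_dir Optional directory of already-acquired ASCII spectra
#'   plus `manifest.csv` per cohort (`cohort1/`, `cohort2/`); when given,
#'   simulation is skipped and the files are ingested instead.
#' @return List with `features` (per cohort), `split`, and `suites` (one
#'   [run_model_suite()] result per task).
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = NULL, spectra_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  panel <- do.call(globin_panel, config$panel %||% list())
  cohorts <- list()
  if (is.null(spectra_dir)) {
    profiles <- do.call(default_profiles, config$profiles %||% list())
    acq <- do.call(acquisition_model, config$acquisition %||% list())
    seeds <- derive_seeds(seed, 2L)
    for (i in 1:2) {
      cname <- paste0("cohort", i)
      cohorts[[cname]] <- simulate_cohort(
        panel, profiles, unlist(config[[cname]]), acq,
        seed = seeds[i], cohort_id = cname)
    }
  } else {
    for (cname in c("cohort1", "cohort2")) {
      cdir <- file.path(spectra_dir, cname)
      manifest <- read_manifest(file.path(cdir, "manifest.csv"))
      spectra <- lapply(manifest$sample_id, function(sid) {
        read_spectrum(file.path(cdir, paste0(sid, ".txt")), sid)
      })
      names(spectra) <- manifest$sample_id
      cohorts[[cname]] <- list(spectra = spectra, manifest = manifest)
    }
  }
  proc <- config$processing %||% list()
  features <- lapply(names(cohorts), function(cname) {
    co <- cohorts[[cname]]
    tryCatch(
      do.call(extract_cohort_features,
              c(list(co$spectra, co$manifest, panel), proc)),
      error = function(e) stopf("stage 'features' failed for %s: %s",
                                cname, conditionMessage(e)))
  })
  names(features) <- names(cohorts)

  split_seed <- derive_seeds(seed + 1L, 1L)
  split <- stratified_split(features$cohort1,
                            ratio = unlist(config$split$ratio %||% c(2, 1)),
                            seed = split_seed)
  tasks <- config$tasks %||% "thal_vs_control"
  suites <- list()
  for (task in tasks) {
    f1 <- features$cohort1
    f2 <- features$cohort2
    f1$task_label <- apply_grouping(f1, task)
    f2$task_label <- apply_grouping(f2, task)
    train <- f1[f1$sample_id %in% split$train_ids, , drop = FALSE]
    test <- f1[f1$sample_id %in% split$test_ids, , drop = FALSE]
    rule <- config$selection[[task]] %||% list(top_k = 5)
    suites[[task]] <- tryCatch(
      run_model_suite(train, test, f2,
                      selection_rule = rule,
                      methods = config$methods %||% CLASSIFIER_METHODS,
                      seed = seed,
                      threshold = config$threshold$type %||% "fixed",
                      threshold_value = config$threshold$value %||% 0.5,
                      label_column = "task_label",
                      positive = "positive"),
      error = function(e) stopf("stage 'models' failed for task %s: %s",
                                task, conditionMessage(e)))
  }
  result <- list(features = features, split = split, suites = suites,
                 config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cname in names(features)) {
      write_feature_table(features[[cname]],
                          file.path(out_dir, paste0("features_", cname, ".csv")))
    }
    for (task in names(suites)) {
      write_model_report(suites[[task]]$reports,
                         file.path(out_dir, paste0("reports_", task, ".json")))
    }
    write_run_record(out_dir, config, seed)
  }
  result
}
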