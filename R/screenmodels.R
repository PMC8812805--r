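#' Rank-based (Mann-Whitney) ROC AUC of a single feature
#'
#' Tie-corrected: equals the fraction of (positive, negative) pairs where the
#' positive value is larger, plus half the tied pairs. Oriented so that the
#' positive class is thalassaemia.
#'
#' @param values Numeric scores or feature values.
#' @param labels Class labels (character/factor with the positive class, or
#'   0/1, or logical).
#' @param positive Positive class value for character labels.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' single_feature_auc(c(1, 2, 3, 4), c("control", "control",
#'                    "thalassaemia", "thalassaemia"))
single_feature_auc <- function(values, labels, positive = POSITIVE_CLASS) {
  y <- as_binary_labels(labels, positive)
  ok <- !is.na(values) & !is.na(y)
  values <- values[ok]; y <- y[ok]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("AUC requires at least one sample of each class")
  }
  r <- rank(values)                      # midranks handle ties
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Rank features by single-feature AUC and select a subset
#'
#' Features are ranked by descending AUC with a deterministic tie-break by
#' canonical column order. The rule is either `list(top_k = k)` (the paper's
#' top-5 screening panel) or `list(auc_min = a)` (the AUC > 0.85 rule of the
#' beta-thalassaemia task).
#'
#' @param feature_table Feature table (data.frame).
#' @param labels Class labels aligned with the rows.
#' @param rule `list(top_k = ...)` or `list(auc_min = ...)`.
#' @param feature_columns Candidate feature columns.
#' @param positive Positive class value.
#' @return Character vector of selected features, ordered by descending AUC;
#'   per-feature AUCs in `attr(, "auc")`.
#' @export
select_features <- function(feature_table, labels, rule = list(top_k = 5L),
                            feature_columns = FEATURE_COLUMNS,
                            positive = POSITIVE_CLASS) {
  feature_columns <- intersect(feature_columns, names(feature_table))
  if (length(feature_columns) < 2L) stopf("need at least 2 candidate features")
  aucs <- vapply(feature_columns, function(f) {
    single_feature_auc(feature_table[[f]], labels, positive)
  }, numeric(1))
  # stable order: descending AUC, ties broken by canonical column position
  o <- order(-aucs, match(feature_columns, FEATURE_COLUMNS))
  ranked <- feature_columns[o]
  ranked_auc <- aucs[o]
  if (!is.null(rule$top_k)) {
    k <- rule$top_k
    if (k > length(ranked)) {
      stopf("top_k = %d exceeds the %d available features", k, length(ranked))
    }
    sel <- ranked[seq_len(k)]
  } else if (!is.null(rule$auc_min)) {
    keep <- ranked_auc > rule$auc_min
    if (!any(keep)) warnf("no feature exceeds auc_min = %g", rule$auc_min)
    sel <- ranked[keep]
  } else {
    stopf("`rule` must contain `top_k` or `auc_min`")
  }
  attr(sel, "auc") <- stats::setNames(ranked_auc, ranked)
  sel
}

#' Stratified 2:1 train/test split
#'
#' Random partition preserving class proportions: per class, the training
#' count is the nearest integer to `train_fraction` times the class size
#' (2/3 for the paper's 2:1 allocation). Reproducible under `seed`.
#'
#' @param manifest Data frame with `sample_id` and the stratification column.
#' @param ratio Length-2 numeric `c(train, test)` allocation (default 2:1).
#' @param seed Seed.
#' @param stratify_on Column to stratify on.
#' @return An object of class `split_plan`: list with `train_ids`,
#'   `test_ids`, `ratio`, `seed`.
#' @export
#' @examples
#' m <- data.frame(sample_id = paste0("s", 1:9),
#'                 class_label = rep(c("thalassaemia", "control"), c(6, 3)))
#' stratified_split(m, seed = 1)
stratified_split <- function(manifest, ratio = c(2, 1), seed = 1L,
                             stratify_on = "class_label") {
  if (!stratify_on %in% names(manifest)) {
    stopf("stratification column '%s' missing", stratify_on)
  }
  classes <- unique(manifest[[stratify_on]])
  if (length(classes) < 2L) stopf("both classes must be present")
  frac <- ratio[1] / sum(ratio)
  train_ids <- character(0)
  with_seed(seed, {
    for (cls in sort(classes)) {
      ids <- manifest$sample_id[manifest[[stratify_on]] == cls]
      if (length(ids) < 3L) {
        stopf("class '%s' has fewer than 3 samples", cls)
      }
      n_train <- round(frac * length(ids))
      train_ids <- c(train_ids, sample(ids, n_train))
    }
  })
  structure(list(train_ids = sort(train_ids),
                 test_ids = sort(setdiff(manifest$sample_id, train_ids)),
                 ratio = ratio, seed = seed, stratify_on = stratify_on),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test (ratio %s, seed %d)\n",
              length(x$train_ids), length(x$test_ids),
              paste(x$ratio, collapse = ":"), x$seed))
  invisible(x)
}

#' ROC AUC with a DeLong 95% confidence interval
#'
#' AUC as in [single_feature_auc()]; the variance is the DeLong nonparametric
#' estimate from the per-observation placement values, and the normal-theory
#' 95% interval is truncated to `[0, 1]`.
#'
#' @param scores Continuous classifier scores.
#' @param labels Class labels.
#' @param positive Positive class value.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric: `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc_ci <- function(scores, labels, positive = POSITIVE_CLASS,
                       conf_level = 0.95) {
  y <- as_binary_labels(labels, positive)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  if (!length(pos) || !length(neg)) {
    stopf("AUC requires both classes")
  }
  auc <- single_feature_auc(scores, y, positive = 1)
  # placement values: V10_i = P(pos_i > neg) with half weight on ties
  psi <- function(a, b) outer(a, b, function(x, y) {
    (x > y) + 0.5 * (x == y)
  })
  M <- psi(pos, neg)
  v10 <- rowMeans(M)
  v01 <- colMeans(M)
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(var_auc, 0))
  c(auc = auc,
    ci_low = max(0, auc - half),
    ci_high = min(1, auc + half))
}

#' Confusion-matrix metrics from scores or counts
#'
#' Thresholds scores at `threshold` (positive when score >= threshold) and
#' reports sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n` and precision `tp/(tp+fp)`, as fractions. Precision is masked
#' (NA) when no sample is called positive.
#'
#' @param scores Continuous scores in `[0, 1]`.
#' @param labels Class labels.
#' @param threshold Decision threshold on the score (default 0.5).
#' @param positive Positive class value.
#' @return List with `confusion` (tp, fn, tn, fp), `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   positive = POSITIVE_CLASS) {
  y <- as_binary_labels(labels, positive)
  call_pos <- scores >= threshold
  metrics_from_confusion(tp = sum(call_pos & y == 1L),
                         fn = sum(!call_pos & y == 1L),
                         tn = sum(!call_pos & y == 0L),
                         fp = sum(call_pos & y == 0L),
                         threshold = threshold)
}

#' @rdname classification_metrics
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @export
#' @examples
#' m <- metrics_from_confusion(tp = 230, fn = 3, tn = 126, fp = 6)
#' round(100 * c(m$sensitivity, m$specificity), 1)  # 98.7 95.5
metrics_from_confusion <- function(tp, fn, tn, fp, threshold = NA_real_) {
  n <- tp + fn + tn + fp
  if (n == 0) stopf("empty confusion matrix")
  list(
    confusion = list(tp = tp, fn = fn, tn = tn, fp = fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / n,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    threshold = threshold
  )
}

# Youden-optimal threshold on training scores: maximises sens + spec - 1.
youden_threshold <- function(scores, labels, positive = POSITIVE_CLASS) {
  y <- as_binary_labels(labels, positive)
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1e-9)
  j <- vapply(cand, function(th) {
    sens <- mean(scores[y == 1L] >= th)
    spec <- mean(scores[y == 0L] < th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

evaluate_model <- function(model, table, label_column, positive, threshold) {
  scores <- predict(model, table)
  labels <- table[[label_column]]
  auc <- roc_auc_ci(scores, labels, positive)
  met <- classification_metrics(scores, labels, threshold, positive)
  list(method = model$method,
       auc = unname(auc["auc"]),
       ci_low = unname(auc["ci_low"]),
       ci_high = unname(auc["ci_high"]),
       sensitivity = met$sensitivity,
       specificity = met$specificity,
       accuracy = met$accuracy,
       precision = met$precision,
       confusion = met$confusion,
       threshold = threshold,
       n = length(scores),
       selected_features = model$features)
}

#' Run the full model-comparison protocol
#'
#' The construction/validation protocol: single-feature AUC ranking and
#' selection on the training table only (leakage guard: the test and
#' validation tables play no part in selection or scaling), fitting of each
#' requested classifier family on the training table, and evaluation on the
#' train, test and (optionally) independent validation tables with AUC,
#' DeLong 95% CI, sensitivity, specificity, accuracy, precision and the
#' confusion matrix. The winning method by validation AUC (test AUC when no
#' validation table is given) is flagged.
#'
#' @param train_table,test_table Feature tables from the construction cohort
#'   split.
#' @param validation_table Independent validation feature table, or `NULL`.
#' @param selection_rule Passed to [select_features()].
#' @param methods Classifier families to run.
#' @param seed Master seed; each method gets a derived sub-seed.
#' @param threshold `"fixed"` uses `threshold_value`; `"youden"` uses the
#'   training-ROC Youden point per method.
#' @param threshold_value Fixed decision threshold (default 0.5).
#' @param label_column,positive Label specification.
#' @param hyper Named list of per-method hyperparameter overrides, e.g.
#'   `list(RF = list(ntree = 200))`.
#' @return An object of class `model_suite`: list with `selected_features`,
#'   `feature_auc`, `reports` (per method, per evaluation set), `best_method`.
#' @export
run_model_suite <- function(train_table, test_table,
                            validation_table = NULL,
                            selection_rule = list(top_k = 5L),
                            methods = CLASSIFIER_METHODS,
                            seed = 1L,
                            threshold = c("fixed", "youden"),
                            threshold_value = 0.5,
                            label_column = "class_label",
                            positive = POSITIVE_CLASS,
                            hyper = list()) {
  threshold <- match.arg(threshold)
  bad <- setdiff(methods, CLASSIFIER_METHODS)
  if (length(bad)) stopf("unknown method(s): %s", paste(bad, collapse = ", "))
  selected <- select_features(train_table, train_table[[label_column]],
                              selection_rule, positive = positive)
  if (!length(selected)) stopf("feature selection returned an empty set")
  seeds <- derive_seeds(seed, length(methods))
  reports <- list()
  for (i in seq_along(methods)) {
    method <- methods[i]
    model <- train_classifier(method, train_table, selected,
                              hyper = hyper[[method]] %||% list(),
                              label_column = label_column,
                              positive = positive, seed = seeds[i])
    th <- if (threshold == "youden") {
      youden_threshold(predict(model, train_table),
                       train_table[[label_column]], positive)
    } else threshold_value
    sets <- list(train = train_table, test = test_table)
    if (!is.null(validation_table)) sets$validation <- validation_table
    reports[[method]] <- lapply(sets, function(tab) {
      evaluate_model(model, tab, label_column, positive, th)
    })
  }
  rank_set <- if (!is.null(validation_table)) "validation" else "test"
  val_auc <- vapply(reports, function(r) r[[rank_set]]$auc, numeric(1))
  structure(list(selected_features = as.character(selected),
                 feature_auc = attr(selected, "auc"),
                 reports = reports,
                 best_method = names(val_auc)[which.max(val_auc)],
                 ranked_on = rank_set,
                 seed = seed),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Model suite on features:", paste(x$selected_features, collapse = ", "),
      "\n")
  for (m in names(x$reports)) {
    r <- x$reports[[m]][[x$ranked_on]]
    cat(sprintf("  %-8s %s AUC %.3f (%.3f-%.3f)  sens %.3f  spec %.3f\n",
                m, x$ranked_on, r$auc, r$ci_low, r$ci_high,
                r$sensitivity, r$specificity))
  }
  cat("Best by", x$ranked_on, "AUC:", x$best_method, "\n")
  invisible(x)
}
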