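test_that("single-feature AUC matches hand examples and handles ties", {
  lab <- c("control", "control", "thalassaemia", "thalassaemia")
  expect_equal(single_feature_auc(1:4, lab), 1)
  expect_equal(single_feature_auc(1:4, c("control", "thalassaemia",
                                         "control", "thalassaemia")), 0.75)
  expect_equal(single_feature_auc(rep(2, 4), lab), 0.5)
  expect_error(single_feature_auc(1:4, rep("control", 4)), "each class")
})

test_that("rank AUC equals the exhaustive pairwise oracle (n <= 12)", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    y <- integer(n)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    # ties made likely by rounding to few levels
    v <- sample(round(rnorm(n), sample(0:1, 1)))
    expect_equal(single_feature_auc(v, y, positive = 1), oracle_auc(v, y))
  }
})

test_that("AUC symmetry: auc(s) + auc(-s) = 1 without ties", {
  set.seed(5)
  v <- rnorm(30)
  y <- rep(c(1, 0), 15)
  expect_equal(single_feature_auc(v, y, positive = 1) +
                 single_feature_auc(-v, y, positive = 1), 1)
})

test_that("feature selection ranks by AUC with deterministic rules", {
  tab <- sim_feature_table(40, 40, delta = 3, n_shift = 2, p = 10)
  labels <- tab$class_label
  top5 <- select_features(tab, labels, list(top_k = 5))
  expect_length(top5, 5)
  # the two shifted columns dominate the ranking
  expect_true(all(c("alpha_1p", "beta_1p") %in% top5[1:2]))
  aucs <- attr(top5, "auc")
  expect_true(!is.unsorted(rev(aucs)))

  strong <- select_features(tab, labels, list(auc_min = 0.9))
  expect_true(all(attr(strong, "auc")[strong] > 0.9))
  expect_warning(none <- select_features(tab, labels, list(auc_min = 1.01)),
                 "no feature")
  expect_length(none, 0)
  expect_error(select_features(tab, labels, list(top_k = 11)), "exceeds")
})

test_that("stratified 2:1 split reproduces the published arithmetic", {
  manifest <- data.frame(
    sample_id = sprintf("p%03d", 1:309),
    class_label = rep(c("thalassaemia", "control"), c(203, 106)))
  plan <- stratified_split(manifest, seed = 1)
  is_thal <- function(ids) grepl("^p(0[0-9][0-9]|1[0-9][0-9]|20[0-3])$", ids)
  n_train_thal <- sum(plan$train_ids %in% manifest$sample_id[1:203])
  expect_length(plan$train_ids, 206)
  expect_length(plan$test_ids, 103)
  expect_equal(n_train_thal, 135)
  expect_equal(sum(plan$test_ids %in% manifest$sample_id[1:203]), 68)
  # disjoint and covering
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_setequal(c(plan$train_ids, plan$test_ids), manifest$sample_id)
  # determinism
  expect_identical(stratified_split(manifest, seed = 1), plan)
  expect_false(identical(stratified_split(manifest, seed = 2)$train_ids,
                         plan$train_ids))
})

test_that("tiny stratified split uses nearest-integer 2/3 allocation", {
  m <- data.frame(sample_id = letters[1:6],
                  class_label = rep(c("thalassaemia", "control"), each = 3))
  plan <- stratified_split(m, seed = 3)
  expect_length(plan$train_ids, 4)
  expect_length(plan$test_ids, 2)
  m2 <- data.frame(sample_id = letters[1:4],
                   class_label = rep(c("thalassaemia", "control"), c(2, 2)))
  expect_error(stratified_split(m2, seed = 1), "fewer than 3")
})

test_that("every classifier family trains, scores sensibly and is seeded", {
  tab <- sim_feature_table(30, 30, delta = 2.5, seed = 2)
  feats <- thalscreen:::FEATURE_COLUMNS[1:5]
  for (method in c("RF", "LR", "SVM", "KNN", "DT", "NB", "Adaboost", "ANN")) {
    hyper <- if (method == "RF") list(ntree = 50) else list()
    model <- train_classifier(method, tab, feats, hyper = hyper, seed = 11)
    scores <- predict(model, tab)
    expect_true(all(scores >= 0 & scores <= 1), label = method)
    # orientation contract on training data
    expect_gte(single_feature_auc(scores, tab$class_label), 0.5)
    # determinism under seed
    model2 <- train_classifier(method, tab, feats, hyper = hyper, seed = 11)
    expect_identical(predict(model2, tab), scores, label = method)
  }
  expect_error(train_classifier("XGB", tab, feats), "unknown method")
})

test_that("LR separates linearly separable toy data perfectly", {
  toy <- data.frame(sample_id = 1:20,
                    class_label = rep(c("thalassaemia", "control"), each = 10),
                    alpha_1p = c(rnorm(10, 5), rnorm(10, -5)),
                    beta_1p = c(rnorm(10, 5), rnorm(10, -5)))
  model <- train_classifier("LR", toy, c("alpha_1p", "beta_1p"))
  expect_equal(single_feature_auc(predict(model, toy), toy$class_label), 1)
})

test_that("masked feature values are a hard error, not silently imputed", {
  tab <- sim_feature_table(10, 10)
  tab$alpha_1p[3] <- NA
  expect_error(train_classifier("LR", tab, c("alpha_1p", "beta_1p")),
               "masked")
})

test_that("DeLong AUC CI behaves at the boundary and under the null", {
  perfect <- c(rnorm(50, 10), rnorm(50, -10))
  y <- rep(c(1, 0), each = 50)
  ci <- roc_auc_ci(perfect, y, positive = 1)
  expect_equal(unname(ci["auc"]), 1)
  expect_equal(unname(ci["ci_high"]), 1)

  for (s in 1:30) {
    set.seed(s)
    auc <- roc_auc_ci(rnorm(1000), rep(c(1, 0), each = 500),
                      positive = 1)["auc"]
    expect_lt(abs(auc - 0.5), 0.06)
  }
})

test_that("DeLong CI width agrees with a bootstrap oracle within 20%", {
  set.seed(77)
  scores <- c(rnorm(60, 1.2), rnorm(60, 0))
  y <- rep(c(1, 0), each = 60)
  ci <- roc_auc_ci(scores, y, positive = 1)
  boot_auc <- vapply(1:2000, function(b) {
    idx <- sample.int(120, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    single_feature_auc(scores[idx], y[idx], positive = 1)
  }, numeric(1))
  bw <- diff(quantile(boot_auc, c(0.025, 0.975), na.rm = TRUE))
  dw <- ci["ci_high"] - ci["ci_low"]
  expect_lt(abs(dw - bw) / bw, 0.2)
})

test_that("confusion metrics reproduce published arithmetic and identities", {
  m <- metrics_from_confusion(tp = 230, fn = 3, tn = 126, fp = 6)
  expect_equal(round(100 * m$sensitivity, 1), 98.7)
  expect_equal(round(100 * m$specificity, 1), 95.5)
  expect_equal(round(100 * m$accuracy, 1), 97.5)
  expect_equal(round(100 * m$precision, 1), 97.5)

  all_right <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(unlist(all_right[c("sensitivity", "specificity",
                                  "accuracy", "precision")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 precision = 1))

  # identities over random confusion matrices
  set.seed(31)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, c(0.4, 0.1, 0.4, 0.1))
    mm <- metrics_from_confusion(cnt[1], cnt[2], cnt[3], cnt[4])
    with(mm$confusion, {
      expect_equal(mm$sensitivity, tp / (tp + fn))
      expect_equal(mm$specificity, tn / (tn + fp))
      expect_equal(mm$accuracy, (tp + tn) / 200)
      if (tp + fp > 0) expect_equal(mm$precision, tp / (tp + fp))
    })
  }

  # no positive calls: precision masked
  none <- classification_metrics(rep(0.1, 6), rep(c(1, 0), 3),
                                 threshold = 0.5, positive = 1)
  expect_true(is.na(none$precision))
})

test_that("run_model_suite respects method lists and flags a winner", {
  train <- sim_feature_table(40, 30, delta = 2, seed = 4)
  test <- sim_feature_table(20, 15, delta = 2, seed = 5)
  val <- sim_feature_table(25, 20, delta = 2, seed = 6)
  suite <- run_model_suite(train, test, val,
                           selection_rule = list(top_k = 3),
                           methods = "LR", seed = 9)
  expect_length(suite$reports, 1)
  expect_named(suite$reports$LR, c("train", "test", "validation"))
  expect_equal(suite$best_method, "LR")
  expect_length(suite$selected_features, 3)
  r <- suite$reports$LR$validation
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_equal(with(r$confusion, tp + fn + tn + fp), r$n)
})

test_that("stronger beta deficits monotonically improve LR validation AUC", {
  panel <- globin_panel()
  # gamma matched across classes so only the beta deficit carries signal
  aucs <- vapply(c(0.95, 0.85, 0.6), function(deficit) {
    profs <- list(
      control = disease_profile("control",
                                c(alpha = 1, beta = 1, gamma = 0.05),
                                between_sample_cv = 0.12),
      beta_thal = disease_profile("beta_thal",
                                  c(alpha = 1, beta = deficit, gamma = 0.05),
                                  between_sample_cv = 0.12))
    co1 <- simulate_cohort(panel, profs, c(control = 24, beta_thal = 24),
                           fast_acq(noise_sd = 0.002), seed = 21,
                           cohort_id = "c1")
    co2 <- simulate_cohort(panel, profs, c(control = 24, beta_thal = 24),
                           fast_acq(noise_sd = 0.002), seed = 22,
                           cohort_id = "c2")
    f1 <- extract_cohort_features(co1$spectra, co1$manifest, panel)
    f2 <- extract_cohort_features(co2$spectra, co2$manifest, panel)
    split <- stratified_split(f1, seed = 1)
    suite <- run_model_suite(f1[f1$sample_id %in% split$train_ids, ],
                             f1[f1$sample_id %in% split$test_ids, ],
                             f2, selection_rule = list(top_k = 5),
                             methods = "LR", seed = 2)
    suite$reports$LR$validation$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
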