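test_that("cross-validation is perfect on a separable phantom", {
  d <- feature_cohort(61, effect_size = 4, n_areas = 3, affected = c(1, 2),
                      n_asd = 10, n_td = 10, n_timepoints = 160)
  cv <- run_cv(d$features, d$labels, scheme = "4-fold", seed = 1)
  expect_equal(cv$metrics[["accuracy"]], 1)
  expect_equal(cv$metrics[["auc"]], 1)
  expect_equal(cv$n_folds, 4)
  # accuracy identity: (sens * n_pos + spec * n_neg) / n
  m <- cv$metrics
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] * 10 + m[["specificity"]] * 10) / 20)
})

test_that("LOSO uses exactly one fold per subject", {
  d <- feature_cohort(62, effect_size = 3, n_areas = 2, affected = 1,
                      n_asd = 5, n_td = 5, n_timepoints = 120)
  cv <- run_cv(d$features, d$labels, scheme = "loso", seed = 1)
  expect_equal(cv$n_folds, 10)
  expect_length(cv$folds, 10)
  expect_true(all(vapply(cv$folds, function(f) f$n_test, numeric(1)) == 1))
})

test_that("accuracy sits at chance under a null effect", {
  accs <- vapply(1:10, function(r) {
    d <- feature_cohort(6200 + r, effect_size = 0, n_areas = 2,
                        affected = 1, n_asd = 15, n_td = 15,
                        n_timepoints = 80, n_bins = 6)
    suppressWarnings(run_cv(d$features, d$labels, scheme = "loso",
                            seed = r, sae_max_iter = 60,
                            screen_folds = 3)$metrics[["accuracy"]])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("repeated cross-validation summarizes the accuracy distribution", {
  # degenerate dataset: one feature profile per class, duplicated, so every
  # refolded repeat gives the identical (perfect) outcome
  f <- array(NA_real_, c(16, 2, 4))
  for (i in 1:16) {
    f[i, , ] <- if (i <= 8) matrix(c(4, 3, 2, 1), 2, 4, byrow = TRUE)
                else matrix(c(0.5, 0.4, 0.3, 0.2), 2, 4, byrow = TRUE)
  }
  f <- f + array(stats::rnorm(16 * 2 * 4, sd = 1e-3), c(16, 2, 4))
  labels <- rep(c("ASD", "TD"), each = 8)
  rep_cv <- suppressWarnings(
    repeat_cv(f, labels, scheme = "2-fold", n_repeats = 5, seed = 1,
              sae_max_iter = 60))
  expect_length(rep_cv$accuracies, 5)
  expect_lte(rep_cv$min, rep_cv$mean)
  expect_lte(rep_cv$mean, rep_cv$max)
  expect_equal(rep_cv$sd, 0)
  expect_equal(rep_cv$mean, 1)
  expect_error(repeat_cv(f, labels, n_repeats = 1), "n_repeats")
})

test_that("hold-out partitions follow largest-remainder stratified sizes", {
  labels100 <- rep(c("ASD", "TD"), each = 50)
  s100 <- holdout_split(labels100, seed = 1)
  expect_equal(lengths(s100), c(train = 60L, validation = 15L, test = 25L))

  labels20 <- rep(c("ASD", "TD"), each = 10)
  s20 <- holdout_split(labels20, seed = 2)
  expect_equal(lengths(s20), c(train = 12L, validation = 3L, test = 5L))

  # disjoint cover
  all_idx <- sort(unname(unlist(s20)))
  expect_equal(all_idx, 1:20)
  # stratification: train split is balanced
  expect_equal(sum(labels20[s20$train] == "ASD"), 6)
  expect_error(holdout_split(c("ASD", "TD", "ASD")), "empty")
})

test_that("hold-out evaluation reports test metrics", {
  d <- feature_cohort(64, effect_size = 4, n_areas = 3, affected = c(1, 2),
                      n_asd = 16, n_td = 16, n_timepoints = 120)
  res <- run_holdout(d$features, d$labels, seed = 3, sae_max_iter = 100)
  expect_true(all(res$metrics[c("accuracy", "sensitivity",
                                "specificity", "auc")] >= 0))
  expect_true(all(res$metrics <= 1))
  expect_gte(res$metrics[["accuracy"]], 0.75)
})

test_that("the permutation p-value follows the add-one counting convention", {
  f_const <- array(1, c(12, 2, 4))
  labels <- rep(c("ASD", "TD"), each = 6)
  p_null <- suppressWarnings(
    permutation_test(f_const, labels, n_shuffles = 9, scheme = "2-fold",
                     seed = 1, sae_max_iter = 30, screen_folds = 2))
  # the reported p is exactly the add-one count of shuffles at or above the
  # observed accuracy, and bounded in [1 / (n + 1), 1]
  expect_equal(p_null$p_value,
               (1 + sum(p_null$shuffled_accuracies >=
                          p_null$observed_accuracy)) / 10)
  expect_gte(p_null$p_value, 1 / 10)
  expect_lte(p_null$p_value, 1)
  # uninformative features: the observed accuracy holds no edge over the
  # bulk of the shuffled ones, so p stays far from the minimum
  expect_gte(p_null$p_value, 0.5)
  expect_error(permutation_test(f_const, labels, n_shuffles = 0), "n_shuffles")
})

test_that("a strongly separated phantom reaches the minimum p-value", {
  d <- feature_cohort(65, effect_size = 4, n_areas = 4, affected = c(1, 2),
                      n_asd = 12, n_td = 12, n_timepoints = 160, n_bins = 8)
  perm <- suppressWarnings(
    permutation_test(d$features, d$labels, n_shuffles = 19,
                     scheme = "4-fold", seed = 2, sae_max_iter = 100))
  expect_equal(perm$p_value, 1 / 20)
  expect_equal(perm$observed_accuracy, 1)
  expect_true(all(perm$shuffled_accuracies < 1))
})

test_that("null permutation p-values are super-uniform", {
  hits <- 0
  n_runs <- 60
  for (r in seq_len(n_runs)) {
    set.seed(8000 + r)
    f <- array(stats::rnorm(12 * 1 * 3), c(12, 1, 3))
    labels <- rep(c("ASD", "TD"), each = 6)
    p <- suppressWarnings(
      permutation_test(f, labels, n_shuffles = 19, scheme = "2-fold",
                       seed = r, sae_max_iter = 25, hidden_size = 10,
                       screen_folds = 2))$p_value
    hits <- hits + (p <= 0.25)
  }
  # P(p <= 0.25) <= 0.25 under the null, allow ~3 sd of Monte-Carlo error
  expect_lte(hits / n_runs, 0.25 + 3 * sqrt(0.25 * 0.75 / n_runs))
})

test_that("the trapezoid AUC equals the pairwise concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("ASD", "ASD", "TD", "TD")), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("ASD", "TD"), 3)), 0.5)

  set.seed(66)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(stats::runif(n), 2)  # deliberate ties
    labels <- sample(c("ASD", "TD"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels),
                 auc_concordance_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("ASD", 4)), "both classes")
})

test_that("the trapezoid AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  scores <- stats::runif(40)
  labels <- sample(c("ASD", "TD"), 40, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("TD", "ASD"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("predictive values reproduce the closed-form results", {
  # frozen oracle: sens .93, spec .89, prev 1/68
  # PPV = .93*(1/68) / (.93*(1/68) + .11*(67/68)) = 0.11204819
  # NPV = .89*(67/68) / (.07*(1/68) + .89*(67/68)) = 0.99882747
  pv <- predictive_values(0.93, 0.89, 1 / 68)
  expect_equal(pv$ppv, 0.11204819, tolerance = 1e-6)
  expect_equal(pv$npv, 0.99882747, tolerance = 1e-6)

  perfect <- predictive_values(1, 1, 0.187)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  # PPV strictly increasing in prevalence when spec < 1
  prevs <- c(0.01, 0.1, 0.187, 0.5, 0.9)
  ppvs <- vapply(prevs, function(p) predictive_values(0.9, 0.8, p)$ppv,
                 numeric(1))
  expect_true(all(diff(ppvs) > 0))

  expect_error(predictive_values(0, 1, 0.5), "denominator")
  expect_error(predictive_values(0.9, 0.9, 0), "prevalence")
  expect_error(predictive_values(1.2, 0.9, 0.5), "0, 1")
})

test_that("behavioural correlations recover exact and null relations", {
  scores <- matrix(stats::runif(30), ncol = 1)
  exact <- behavioral_correlation(scores, 2 * scores[, 1] + 1)
  expect_equal(exact$r, 1, tolerance = 1e-12)

  # null: independent behavioural scores
  set.seed(68)
  rs <- vapply(1:50, function(r) {
    behavioral_correlation(matrix(stats::runif(100), ncol = 1),
                           stats::rnorm(100))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)

  expect_error(behavioral_correlation(matrix(1:2, ncol = 1), c(1, 2)),
               "3 paired")
  expect_warning(behavioral_correlation(matrix(rep(1, 10), ncol = 1),
                                        stats::rnorm(10)), "zero variance")
})

test_that("area power tracks behavioural severity in affected phantoms", {
  positives <- 0
  for (r in 1:50) {
    spec <- phantom_spec(grid_shape = c(8, 8, 4), n_timepoints = 80,
                         n_areas = 3, affected_areas = 1, effect_size = 2,
                         n_asd = 40, n_td = 0, seed = 9000 + r)
    cohort <- simulate_cohort(spec, return_volumes = FALSE)
    bp <- truth_band_power(cohort)
    res <- behavioral_correlation(bp[, 1, drop = FALSE], cohort$behavioral)
    positives <- positives + (res$r > 0)
  }
  expect_gte(positives, 45)
})
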