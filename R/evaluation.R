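# Evaluation: cross-validation, repeated runs, hold-out, label-permutation
# significance, ROC/AUC, prevalence-adjusted predictive values and
# behavioural correlation. All schemes derive their per-run seeds from one
# root seed via derive_seed(root, counter).

scheme_folds <- function(scheme, n) {
  switch(scheme,
         "2-fold" = 2L, "4-fold" = 4L, "10-fold" = 10L,
         "loso" = as.integer(n),
         stop(sprintf("unknown scheme '%s'", scheme), call. = FALSE))
}

classification_metrics <- function(pred, labels) {
  pos <- labels == "ASD"
  c(accuracy = mean(pred == pos),
    sensitivity = mean(pred[pos]),
    specificity = mean(!pred[!pos]))
}

# Shared CV engine. `encoders_by_fold`, when supplied, carries the
# unsupervised per-area encoder stage for each fold so that only the
# label-dependent SVM stage is refit (used by permutation_test, where the
# labels change but the data do not).
cv_engine <- function(features, labels, folds, seed, cad_args,
                      encoders_by_fold = NULL) {
  k <- max(folds)
  n <- length(labels)
  pooled_scores <- rep(NA_real_, n)
  pooled_pred <- rep(NA, n)
  fold_records <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    train_labels <- labels[!test]
    if (length(unique(train_labels)) < 2) {
      # a label permutation can empty one class from a training fold; the
      # only fittable classifier is the base rate of the remaining class
      base <- mean(train_labels == "ASD")
      pooled_scores[test] <- base
      pooled_pred[test] <- base > 0.5
      fold_records[[f]] <- list(fold = f, n_test = sum(test),
                                selected_areas = integer(0))
      next
    }
    enc <- if (is.null(encoders_by_fold)) NULL else encoders_by_fold[[f]]
    model <- suppressWarnings(do.call(cad_fit, c(
      list(features = features[!test, , , drop = FALSE],
           labels = train_labels,
           encoders = enc, seed = derive_seed(seed, f)),
      cad_args)))
    pred <- predict(model, features[test, , , drop = FALSE])
    pooled_scores[test] <- pred$score
    pooled_pred[test] <- pred$class == "ASD"
    fold_records[[f]] <- list(fold = f, n_test = sum(test),
                              selected_areas = model$selected_areas)
  }
  metrics <- classification_metrics(pooled_pred, labels)
  list(metrics = metrics, scores = pooled_scores, pred = pooled_pred,
       folds = fold_records)
}

# Train the unsupervised encoder stage (standardization + SAE) for every
# area on the training rows of each fold.
fold_encoders <- function(features, folds, seed, cad_args) {
  hyper <- list(hidden_size = 10, sparsity_target = 0.3, sparsity_weight = 1,
                weight_decay = 1e-4, sae_max_iter = 200)
  hyper[names(cad_args)[names(cad_args) %in% names(hyper)]] <-
    cad_args[names(cad_args) %in% names(hyper)]
  lapply(seq_len(max(folds)), function(f) {
    x <- features[folds != f, , , drop = FALSE]
    lapply(seq_len(dim(x)[2]), function(a) {
      xa <- x[, a, , drop = TRUE]
      if (is.null(dim(xa))) xa <- matrix(xa, ncol = 1)
      center <- colMeans(xa)
      scl <- apply(xa, 2, stats::sd)
      scl[scl == 0] <- 1
      sae <- sae_fit(scale(xa, center, scl), hyper$hidden_size,
                     hyper$sparsity_target, hyper$sparsity_weight,
                     hyper$weight_decay, max_iter = hyper$sae_max_iter,
                     seed = derive_seed(seed, f * 1000 + a))
      list(center = center, scale = scl, sae = sae)
    })
  })
}

#' Cross-validated evaluation of the diagnosis pipeline
#'
#' Stratified k-fold (or leave-one-subject-out) cross-validation: the full
#' label-dependent pipeline (autoencoders, SVMs, area screening) is refit on
#' every training fold, out-of-fold subjects are diagnosed, and the pooled
#' out-of-fold global diagnoses give accuracy, sensitivity and specificity;
#' AUC is computed from the pooled fused membership scores.
#'
#' @param features subjects x areas x bins feature array.
#' @param labels diagnosis labels.
#' @param scheme one of `"2-fold"`, `"4-fold"`, `"10-fold"`, `"loso"`.
#' @param seed root seed (folding and per-fold model seeds derive from it).
#' @param ... further arguments to [cad_fit()].
#' @return an object of class `cad_cv`: `metrics` (accuracy, sensitivity,
#'   specificity, auc), `scheme`, `n_folds`, `scores` (pooled out-of-fold
#'   fused scores), `folds` (per-fold records).
#' @export
run_cv <- function(features, labels,
                   scheme = c("4-fold", "2-fold", "10-fold", "loso"),
                   seed = 1, ...) {
  scheme <- match.arg(scheme)
  features <- as_feature_array(features)
  labels <- as_diagnosis(labels)
  k <- scheme_folds(scheme, length(labels))
  folds <- if (scheme == "loso") seq_along(labels)
           else make_folds(labels, k, seed = seed)
  res <- cv_engine(features, labels, folds, seed, list(...))
  auc <- roc_auc(res$scores, labels)
  structure(list(metrics = c(res$metrics, auc = auc), scheme = scheme,
                 n_folds = k, scores = res$scores, folds = res$folds,
                 labels = labels, seed = seed), class = "cad_cv")
}

#' @export
print.cad_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s cross-validation (%d folds, n = %d)\n", x$scheme,
              x$n_folds, length(x$labels)))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.4f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["auc"]))
  invisible(x)
}

#' Repeated cross-validation summary
#'
#' Re-runs [run_cv()] `n_repeats` times with independently derived seeds
#' (hence fresh fold assignments) and summarizes the accuracy distribution.
#'
#' @inheritParams run_cv
#' @param n_repeats number of repetitions (default 100).
#' @return list with `min`, `max`, `mean`, `sd` of accuracy and the
#'   per-repeat `accuracies`.
#' @export
repeat_cv <- function(features, labels, scheme = "4-fold", n_repeats = 100,
                      seed = 1, ...) {
  if (n_repeats < 2) stop("n_repeats must be >= 2", call. = FALSE)
  acc <- vapply(seq_len(n_repeats), function(r) {
    run_cv(features, labels, scheme = scheme,
           seed = derive_seed(seed, r), ...)$metrics[["accuracy"]]
  }, numeric(1))
  list(min = min(acc), max = max(acc), mean = mean(acc), sd = stats::sd(acc),
       accuracies = acc)
}

#' Stratified train/validation/test partition
#'
#' Overall partition sizes follow the largest-remainder rule on the
#' fractions; subjects are then dealt to the partitions in a seeded,
#' class-interleaved order so each partition is (near-)stratified while the
#' totals stay exact. Partitions are disjoint and cover all subjects.
#'
#' @param labels diagnosis labels.
#' @param fractions train/validation/test fractions summing to 1 (default
#'   0.60 / 0.15 / 0.25).
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
holdout_split <- function(labels, fractions = c(0.60, 0.15, 0.25), seed = 1) {
  labels <- as_diagnosis(labels)
  n <- length(labels)
  sizes <- largest_remainder(n, fractions)
  if (any(sizes == 0)) {
    stop("a partition would be empty at this sample size", call. = FALSE)
  }
  order_interleaved <- with_seed(seed, {
    by_class <- lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      idx[sample.int(length(idx))]
    })
    counts <- lengths(by_class)
    taken <- c(0L, 0L)
    out <- integer(n)
    for (i in seq_len(n)) {
      # take next subject from the class lagging most behind its share
      deficit <- (taken + 1) / counts
      cl <- which.min(ifelse(taken < counts, deficit, Inf))
      taken[cl] <- taken[cl] + 1L
      out[i] <- by_class[[cl]][taken[cl]]
    }
    out
  })
  list(train = sort(order_interleaved[seq_len(sizes[1])]),
       validation = sort(order_interleaved[sizes[1] + seq_len(sizes[2])]),
       test = sort(order_interleaved[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Hold-out evaluation
#'
#' Fits the diagnosis model on the training partition (hyper-parameter grids,
#' when supplied, are scored on the validation partition) and reports metrics
#' on the held-out test partition.
#'
#' @inheritParams run_cv
#' @param fractions passed to [holdout_split()].
#' @return list with `metrics` (accuracy, sensitivity, specificity, auc),
#'   `split` and the fitted `model`.
#' @export
run_holdout <- function(features, labels, fractions = c(0.60, 0.15, 0.25),
                        seed = 1, ...) {
  features <- as_feature_array(features)
  labels <- as_diagnosis(labels)
  split <- holdout_split(labels, fractions, seed)
  trainval <- c(split$train, split$validation)
  model <- suppressWarnings(
    cad_fit(features[trainval, , , drop = FALSE], labels[trainval],
            seed = derive_seed(seed, 1), ...))
  pred <- predict(model, features[split$test, , , drop = FALSE])
  metrics <- classification_metrics(pred$class == "ASD", labels[split$test])
  auc <- roc_auc(pred$score, labels[split$test])
  list(metrics = c(metrics, auc = auc), split = split, model = model)
}

#' Label-permutation significance of classifier accuracy
#'
#' Shuffles the diagnosis labels to simulate an uninformative data set,
#' re-evaluates the classifier under each shuffle, and reports
#' `p = (1 + #\{shuffled accuracy >= observed accuracy\}) /
#' (1 + n_shuffles)`. The fold partition is held fixed across shuffles, and
#' because the autoencoder stage is unsupervised its per-fold encoders are
#' trained once and reused; only the label-dependent SVM and screening
#' stages are refit per shuffle, so the computation is exact.
#'
#' @inheritParams run_cv
#' @param n_shuffles number of label shuffles (default 99, giving a minimum
#'   attainable p of 0.01).
#' @return an object of class `cad_permutation`: `p_value`,
#'   `observed_accuracy`, `shuffled_accuracies`, `n_shuffles`.
#' @export
permutation_test <- function(features, labels, n_shuffles = 99,
                             scheme = "4-fold", seed = 1, ...) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  features <- as_feature_array(features)
  labels <- as_diagnosis(labels)
  k <- scheme_folds(scheme, length(labels))
  # folds must not depend on the labels: the observed labeling and its
  # shuffles are then exchangeable under the null, which makes the p-value
  # exactly valid (a label-stratified partition would privilege the observed
  # labeling)
  folds <- if (scheme == "loso") seq_along(labels)
           else with_seed(seed, sample(rep_len(seq_len(k), length(labels))))
  cad_args <- list(...)
  encoders <- fold_encoders(features, folds, seed, cad_args)
  observed <- cv_engine(features, labels, folds, seed, cad_args,
                        encoders)$metrics[["accuracy"]]
  shuffled <- with_seed(derive_seed(seed, 42), {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample(labels)
      cv_engine(features, perm, folds, seed, cad_args,
                encoders)$metrics[["accuracy"]]
    }, numeric(1))
  })
  structure(list(p_value = (1 + sum(shuffled >= observed)) / (1 + n_shuffles),
                 observed_accuracy = observed,
                 shuffled_accuracies = shuffled, n_shuffles = n_shuffles,
                 scheme = scheme), class = "cad_permutation")
}

#' @export
print.cad_permutation <- function(x, ...) {
  cat(sprintf(paste0("Label-permutation test (%s, %d shuffles): observed ",
                     "accuracy %.3f, p = %.4g\n"),
              x$scheme, x$n_shuffles, x$observed_accuracy, x$p_value))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC of membership scores with autism as the
#' positive class; equal to the pairwise concordance probability with ties
#' counted one half.
#'
#' @param scores numeric membership (or fused) scores.
#' @param labels diagnosis labels; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_diagnosis(labels)
  pos <- labels == "ASD"
  if (!any(pos) || all(pos)) {
    stop("both classes are required for a ROC curve", call. = FALSE)
  }
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the (0, 0) corner to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as_diagnosis(labels)
  pos <- labels == "ASD"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Prevalence-adjusted predictive values
#'
#' Positive and negative predictive values of a diagnostic test at a given
#' population prevalence:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = spec * (1 - prev) / ((1 - sens) * prev + spec * (1 - prev))`.
#' Reference prevalences for autism are 1/68 (general US population) and
#' 0.187 (younger siblings of diagnosed children).
#'
#' @param sens,spec classifier sensitivity and specificity in `[0, 1]`.
#' @param prevalence prior probability of diagnosis, strictly inside (0, 1).
#' @return an object of class `prevalence_report`: `prevalence`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`.
#' @export
predictive_values <- function(sens, spec, prevalence) {
  if (any(c(sens, spec) < 0) || any(c(sens, spec) > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  ppv_den <- sens * prevalence + (1 - spec) * (1 - prevalence)
  npv_den <- (1 - sens) * prevalence + spec * (1 - prevalence)
  if (ppv_den == 0 || npv_den == 0) {
    stop("predictive value undefined: zero denominator at this prevalence",
         call. = FALSE)
  }
  structure(list(prevalence = prevalence,
                 ppv = sens * prevalence / ppv_den,
                 npv = spec * (1 - prevalence) / npv_den,
                 sensitivity = sens, specificity = spec),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf(paste0("At prevalence %.4g (sens %.3f, spec %.3f): ",
                     "PPV %.4f, NPV %.4f\n"),
              x$prevalence, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Correlation of area membership scores with behavioural scores
#'
#' Pearson correlation, per atlas area, between the area's membership score
#' and a behavioural total/severity score (e.g. ADOS), over subjects with
#' both values available.
#'
#' @param area_scores numeric matrix, subjects x areas.
#' @param behavioral_scores numeric vector (NA allowed; pairs with NA are
#'   dropped).
#' @return data frame with columns `area`, `r`, `p_value`, `n`. Areas with
#'   zero variance in either vector yield NA with a warning.
#' @export
behavioral_correlation <- function(area_scores, behavioral_scores) {
  if (is.vector(area_scores)) area_scores <- matrix(area_scores, ncol = 1)
  keep <- is.finite(behavioral_scores)
  area_scores <- area_scores[keep, , drop = FALSE]
  behavioral_scores <- behavioral_scores[keep]
  if (length(behavioral_scores) < 3) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  rows <- lapply(seq_len(ncol(area_scores)), function(a) {
    s <- area_scores[, a]
    if (stats::sd(s) == 0 || stats::sd(behavioral_scores) == 0) {
      warning(sprintf("area %d: zero variance, correlation undefined", a))
      return(data.frame(area = a, r = NA_real_, p_value = NA_real_,
                        n = length(s)))
    }
    ct <- stats::cor.test(s, behavioral_scores, method = "pearson")
    data.frame(area = a, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(s))
  })
  do.call(rbind, rows)
}
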