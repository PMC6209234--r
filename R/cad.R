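# The diagnostic core: per-area sparse autoencoder + probabilistic RBF-SVM,
# area screening by stand-alone diagnostic performance, and winner-takes-all
# fusion of the significant areas' membership scores.

#' Stand-alone diagnostic performance of each area
#'
#' Thresholds membership scores at `threshold` (score >= threshold means
#' autism) and computes sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)` per area.
#'
#' @param scores numeric vector (one area) or matrix (subjects x areas) of
#'   membership scores.
#' @param labels diagnosis labels; both classes must be present.
#' @param threshold score binarization threshold (default 0.5).
#' @return data frame with columns `area`, `sensitivity`, `specificity`.
#' @export
area_performance <- function(scores, labels, threshold = 0.5) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  labels <- as_diagnosis(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes are required to compute sensitivity and specificity",
         call. = FALSE)
  }
  pos <- labels == "ASD"
  res <- apply(scores, 2, function(s) {
    call_asd <- s >= threshold
    c(sensitivity = mean(call_asd[pos]), specificity = mean(!call_asd[!pos]))
  })
  data.frame(area = seq_len(ncol(scores)), sensitivity = res[1, ],
             specificity = res[2, ], row.names = NULL)
}

#' Screen areas by diagnostic performance
#'
#' Keeps areas whose stand-alone sensitivity AND specificity both exceed the
#' threshold (strictly). An empty selection falls back to all areas with a
#' warning so that fusion always has input.
#'
#' @param performances an [area_performance()] data frame.
#' @param threshold empirical screening threshold (default 0.65).
#' @return integer vector of selected area ids.
#' @export
select_significant_areas <- function(performances, threshold = 0.65) {
  keep <- performances$area[performances$sensitivity > threshold &
                              performances$specificity > threshold]
  if (!length(keep)) {
    warning("no area passed the screening threshold; falling back to all areas")
    keep <- performances$area
  }
  as.integer(keep)
}

#' Winner-takes-all global diagnosis
#'
#' Averages the membership scores of the selected (significant) areas per
#' subject; the class with the larger average wins, i.e. autism if and only
#' if the mean score exceeds 0.5. An exact tie at 0.5 is resolved to TD
#' (conservative toward no diagnosis).
#'
#' @param area_scores numeric vector (one subject) or matrix (subjects x
#'   areas) of membership scores.
#' @param selected_areas nonempty integer vector of area indices to fuse.
#' @return list with `label` (factor, levels TD/ASD) and `mean_score`.
#' @export
global_diagnosis <- function(area_scores, selected_areas) {
  if (!length(selected_areas)) {
    stop("selected_areas must be nonempty", call. = FALSE)
  }
  if (is.vector(area_scores)) area_scores <- matrix(area_scores, nrow = 1)
  m <- rowMeans(area_scores[, selected_areas, drop = FALSE])
  list(label = factor(ifelse(m > 0.5, "ASD", "TD"), levels = c("TD", "ASD")),
       mean_score = m)
}

#' Personalized per-area diagnosis report
#'
#' One row per area with the raw membership score (no re-scaling) and a color
#' bin for map rendering: `n_bins` equal-width half-open bins over `[0, 1]`
#' (the last bin closed), indexed from 0 (coldest, least autism-like) to
#' `n_bins - 1` (hottest).
#'
#' @param subject_scores numeric vector of membership scores in `[0, 1]`.
#' @param global_label optional precomputed global label; default recomputed
#'   from all areas with [global_diagnosis()].
#' @param n_bins number of color bins (default 8).
#' @param subject_id identifier recorded in the report.
#' @return an object of class `cad_report`: data frame with columns `area`,
#'   `score`, `color_bin`, plus attributes `subject_id`, `global_label`,
#'   `mean_score`, `n_bins`.
#' @export
personalized_report <- function(subject_scores, global_label = NULL,
                                n_bins = 8, subject_id = "subject") {
  s <- as.numeric(subject_scores)
  if (any(s < 0 | s > 1)) {
    stop("membership scores must lie in [0, 1]", call. = FALSE)
  }
  bins <- pmin(floor(s * n_bins), n_bins - 1L)
  fused <- global_diagnosis(s, seq_along(s))
  if (is.null(global_label)) global_label <- fused$label
  out <- data.frame(area = seq_along(s), score = s, color_bin = as.integer(bins))
  attr(out, "subject_id") <- subject_id
  attr(out, "global_label") <- as.character(global_label)
  attr(out, "mean_score") <- fused$mean_score
  attr(out, "n_bins") <- as.integer(n_bins)
  class(out) <- c("cad_report", "data.frame")
  out
}

#' @export
print.cad_report <- function(x, ...) {
  cat(sprintf("Personalized report for %s: global %s (mean score %.3f)\n",
              attr(x, "subject_id"), attr(x, "global_label"),
              attr(x, "mean_score")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Fit the label-dependent stage for one area: SVM on encodings, screening
# scores from out-of-fold internal CV (the SAE is unsupervised and fixed).
fit_area_stage <- function(enc, labels, kernel_scale, box_constraint,
                           screen_folds, seed) {
  n <- length(labels)
  k <- min(screen_folds, min(table(labels)))
  oof <- rep(NA_real_, n)
  if (k >= 2) {
    folds <- make_folds(labels, k, seed = seed)
    for (f in seq_len(k)) {
      test <- folds == f
      svm_f <- train_area_svm(enc[!test, , drop = FALSE], labels[!test],
                              kernel_scale, box_constraint)
      oof[test] <- membership_score(svm_f, enc[test, , drop = FALSE])
    }
  } else {
    svm_all <- train_area_svm(enc, labels, kernel_scale, box_constraint)
    oof <- membership_score(svm_all, enc)
  }
  svm <- train_area_svm(enc, labels, kernel_scale, box_constraint)
  list(svm = svm, oof = oof)
}

#' Fit the personalized autism diagnosis model
#'
#' The diagnostic core of the pipeline. For every atlas area it standardizes
#' the PSD feature bins, trains a sparse autoencoder ([sae_fit()]) for a
#' higher-level encoding, trains a probabilistic RBF-SVM
#' ([train_area_svm()]) on the encodings, and computes the area's stand-alone
#' diagnostic performance from out-of-fold membership scores of an internal
#' stratified cross-validation on the training data (the autoencoder, being
#' unsupervised, is trained once per area; only the SVM is refit per internal
#' fold). Areas with both sensitivity and specificity above the screening
#' threshold are retained as significant; their mean membership score drives
#' the winner-takes-all global diagnosis in [predict.cad_model()].
#'
#' Optional grid searches ([grid_search_sae()], [grid_search_svm()]) can be
#' enabled per area by supplying grids.
#'
#' @param features numeric array, subjects x areas x frequency bins (e.g.
#'   from [features_from_truth()] or stacked [extract_features()] rows), or a
#'   subjects x bins matrix for a single area.
#' @param labels diagnosis labels ("ASD"/"TD").
#' @param hidden_size,sparsity_target,sparsity_weight,weight_decay
#'   autoencoder hyper-parameters (see [sae_fit()]).
#' @param sae_max_iter L-BFGS iteration cap for each area's autoencoder.
#' @param kernel_scale,box_constraint SVM hyper-parameters (defaults 5 and
#'   12, the reference pipeline's selected values).
#' @param sae_grid,svm_grid optional named lists of grids to trigger per-area
#'   hyper-parameter search (elements as the grid arguments of the two search
#'   functions).
#' @param screen_threshold significant-area screening threshold (default
#'   0.65).
#' @param score_threshold membership binarization threshold for per-area
#'   sensitivity/specificity (default 0.5).
#' @param screen_folds internal CV folds for screening scores.
#' @param encoders optional precomputed per-area encoder list (as stored in a
#'   fitted model's `$areas`); reused instead of retraining the unsupervised
#'   stage, e.g. across label permutations.
#' @param seed root seed; per-area seeds are derived from it.
#' @return an object of class `cad_model`.
#' @seealso [predict.cad_model()], [run_cv()], [permutation_test()]
#' @export
cad_fit <- function(features, labels,
                    hidden_size = 10, sparsity_target = 0.3,
                    sparsity_weight = 1, weight_decay = 1e-4,
                    sae_max_iter = 200,
                    kernel_scale = 5, box_constraint = 12,
                    sae_grid = NULL, svm_grid = NULL,
                    screen_threshold = 0.65, score_threshold = 0.5,
                    screen_folds = 5, encoders = NULL, seed = 1) {
  if (length(dim(features)) == 2) {
    features <- array(features, c(nrow(features), 1, ncol(features)))
  }
  stopifnot(length(dim(features)) == 3)
  labels <- as_diagnosis(labels)
  if (length(labels) != dim(features)[1]) {
    stop("feature rows and labels disagree", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  n_areas <- dim(features)[2]
  areas <- vector("list", n_areas)
  oof_scores <- matrix(NA_real_, length(labels), n_areas)
  for (a in seq_len(n_areas)) {
    seed_a <- derive_seed(seed, a)
    xa <- features[, a, , drop = TRUE]
    if (is.null(dim(xa))) xa <- matrix(xa, ncol = 1)
    if (is.null(encoders)) {
      center <- colMeans(xa)
      scale <- apply(xa, 2, stats::sd)
      scale[scale == 0] <- 1
      xs <- scale(xa, center, scale)
      hyper <- list(hidden_size = hidden_size,
                    sparsity_target = sparsity_target,
                    sparsity_weight = sparsity_weight,
                    weight_decay = weight_decay)
      if (!is.null(sae_grid)) {
        hyper <- do.call(grid_search_sae,
                         c(list(x = xs, seed = seed_a), sae_grid))
      }
      sae <- sae_fit(xs, hyper$hidden_size, hyper$sparsity_target,
                     hyper$sparsity_weight, hyper$weight_decay,
                     max_iter = sae_max_iter, seed = seed_a)
      enc_area <- list(center = center, scale = scale, sae = sae)
    } else {
      enc_area <- encoders[[a]][c("center", "scale", "sae")]
      xs <- scale(xa, enc_area$center, enc_area$scale)
    }
    enc <- predict(enc_area$sae, xs, type = "encode")
    ks <- kernel_scale
    bc <- box_constraint
    if (!is.null(svm_grid)) {
      val <- make_folds(labels, 4, seed = seed_a) == 1
      gs <- do.call(grid_search_svm,
                    c(list(train_x = enc[!val, , drop = FALSE],
                           train_labels = labels[!val],
                           val_x = enc[val, , drop = FALSE],
                           val_labels = labels[val]),
                      svm_grid))
      ks <- gs$kernel_scale
      bc <- gs$box_constraint
    }
    stage <- fit_area_stage(enc, labels, ks, bc, screen_folds, seed_a)
    oof_scores[, a] <- stage$oof
    areas[[a]] <- c(enc_area, list(svm = stage$svm))
  }
  performance <- area_performance(oof_scores, labels, score_threshold)
  selected <- select_significant_areas(performance, screen_threshold)
  structure(list(areas = areas, performance = performance,
                 selected_areas = selected, oof_scores = oof_scores,
                 labels = labels,
                 config = list(hidden_size = hidden_size,
                               sparsity_target = sparsity_target,
                               sparsity_weight = sparsity_weight,
                               weight_decay = weight_decay,
                               sae_max_iter = sae_max_iter,
                               kernel_scale = kernel_scale,
                               box_constraint = box_constraint,
                               screen_threshold = screen_threshold,
                               score_threshold = score_threshold,
                               screen_folds = screen_folds, seed = seed),
                 call = match.call()), class = "cad_model")
}

#' @export
print.cad_model <- function(x, ...) {
  cat(sprintf("Autism CAD model: %d areas, %d training subjects (%d ASD, %d TD)\n",
              length(x$areas), length(x$labels), sum(x$labels == "ASD"),
              sum(x$labels == "TD")))
  cat(sprintf("  significant areas (sens & spec > %.2f): %s\n",
              x$config$screen_threshold,
              paste(x$selected_areas, collapse = ", ")))
  invisible(x)
}

#' @export
summary.cad_model <- function(object, ...) {
  perf <- object$performance
  perf$selected <- perf$area %in% object$selected_areas
  structure(list(performance = perf, config = object$config,
                 n = length(object$labels)), class = "summary.cad_model")
}

#' @export
print.summary.cad_model <- function(x, ...) {
  cat(sprintf("Autism CAD model (n = %d)\n", x$n))
  cat(sprintf("  SVM: kernel scale %g, box constraint %g; screening > %.2f\n",
              x$config$kernel_scale, x$config$box_constraint,
              x$config$screen_threshold))
  print.data.frame(x$performance, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict diagnoses with a fitted CAD model
#'
#' Computes per-area membership scores for new subjects, fuses the model's
#' significant areas by winner-takes-all averaging, and returns the global
#' labels.
#'
#' @param object a fitted `cad_model`.
#' @param newdata feature array, subjects x areas x bins (areas must match
#'   the fitted model).
#' @param type `"response"` for a data frame of fused scores and labels,
#'   `"scores"` for the subjects x areas membership matrix.
#' @param ... unused.
#' @return see `type`; the `"response"` data frame carries the score matrix
#'   in its `"area_scores"` attribute.
#' @export
predict.cad_model <- function(object, newdata,
                              type = c("response", "scores"), ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 2) {
    newdata <- array(newdata, c(nrow(newdata), 1, ncol(newdata)))
  }
  if (dim(newdata)[2] != length(object$areas)) {
    stop("newdata area count does not match the fitted model", call. = FALSE)
  }
  n <- dim(newdata)[1]
  scores <- matrix(NA_real_, n, length(object$areas))
  for (a in seq_along(object$areas)) {
    ar <- object$areas[[a]]
    xa <- newdata[, a, , drop = TRUE]
    if (is.null(dim(xa))) xa <- matrix(xa, ncol = length(ar$center))
    xs <- scale(xa, ar$center, ar$scale)
    enc <- predict(ar$sae, xs, type = "encode")
    scores[, a] <- membership_score(ar$svm, enc)
  }
  if (type == "scores") return(scores)
  fused <- global_diagnosis(scores, object$selected_areas)
  out <- data.frame(subject = seq_len(n), score = fused$mean_score,
                    class = fused$label)
  attr(out, "area_scores") <- scores
  out
}
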