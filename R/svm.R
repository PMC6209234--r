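# Per-area probabilistic RBF-SVM. The soft-margin solver is libsvm (via
# e1071); the probabilistic membership layer on top is the logistic
# transform of the signed decision value, oriented so that positive means
# the autism class.

#' Train a per-area RBF support vector machine
#'
#' Soft-margin C-classification with a radial basis kernel
#' `K(x, y) = exp(-||x - y||^2 / kernel_scale^2)` (so `gamma =
#' 1 / kernel_scale^2`). Defaults are kernel scale 5 and box constraint 12,
#' the values selected by grid search in the reference pipeline; both are
#' recorded in the returned model. The decision function is oriented so that
#' positive values point toward the autism class.
#'
#' @param x numeric matrix of (encoded) feature rows.
#' @param labels diagnosis labels ("ASD"/"TD"); both classes must be present.
#' @param kernel_scale RBF kernel scale (search range 1--20).
#' @param box_constraint soft-margin cost C (search range 1--100).
#' @return an object of class `area_svm`.
#' @export
train_area_svm <- function(x, labels, kernel_scale = 5, box_constraint = 12) {
  x <- as.matrix(x)
  labels <- as_diagnosis(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training data", call. = FALSE)
  }
  # inverse-frequency class weights: balanced folds are unaffected, while
  # slightly imbalanced folds (e.g. leave-one-subject-out) do not tilt the
  # margin toward the majority class
  counts <- table(droplevels(labels))
  weights <- as.numeric(length(labels) / (2 * counts))
  names(weights) <- names(counts)
  fit <- e1071::svm(x, labels, type = "C-classification", kernel = "radial",
                    gamma = 1 / kernel_scale^2, cost = box_constraint,
                    class.weights = weights, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  orient <- if (mean(dv[labels == "ASD"]) >= mean(dv[labels == "TD"])) 1 else -1
  structure(list(fit = fit, orient = orient, kernel_scale = kernel_scale,
                 box_constraint = box_constraint), class = "area_svm")
}

#' @export
print.area_svm <- function(x, ...) {
  cat(sprintf(paste0("Area RBF-SVM: kernel scale %g, box constraint %g, ",
                     "%d support vectors\n"),
              x$kernel_scale, x$box_constraint, x$fit$tot.nSV))
  invisible(x)
}

#' Signed decision values of an area SVM
#'
#' Distance-like decision values of points relative to the classification
#' hyperplane, positive toward the autism class.
#'
#' @param svm an `area_svm`.
#' @param x numeric matrix of points.
#' @return numeric vector.
#' @export
decision_values <- function(svm, x) {
  stopifnot(inherits(svm, "area_svm"))
  x <- as.matrix(x)
  dv <- attr(stats::predict(svm$fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  svm$orient * dv
}

#' Logistic membership from a signed decision value
#'
#' `1 / (1 + exp(-d))`: 0.5 on the hyperplane, strictly inside (0, 1)
#' everywhere, monotone in the decision value.
#'
#' @param d numeric vector of signed decision values.
#' @return numeric vector in (0, 1).
#' @export
decision_membership <- function(d) stats::plogis(d)

#' Autism-class membership score
#'
#' The probabilistic output of the area classifier: the sigmoid of the signed
#' distance between the sample and the classification hyperplane, oriented so
#' that scores above 0.5 favor the autism class.
#'
#' @param svm an `area_svm`.
#' @param x numeric matrix (or vector) of encoded points.
#' @return numeric vector of scores in (0, 1).
#' @export
membership_score <- function(svm, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  decision_membership(decision_values(svm, x))
}

#' Grid search for SVM hyper-parameters
#'
#' Trains one SVM per (kernel scale, box constraint) pair on the training
#' split and scores classification accuracy on the validation split. Ties
#' break toward the smallest kernel scale, then the smallest box constraint.
#' Default grids are the model-selection ranges 1--20 and 1--100.
#'
#' @param train_x,train_labels training split.
#' @param val_x,val_labels validation split (must contain both classes).
#' @param kernel_scales,box_constraints candidate grids.
#' @return list with `kernel_scale`, `box_constraint`, `accuracy` and the
#'   full `results` data frame.
#' @export
grid_search_svm <- function(train_x, train_labels, val_x, val_labels,
                            kernel_scales = 1:20, box_constraints = 1:100) {
  if (!length(kernel_scales) || !length(box_constraints)) {
    stop("empty hyper-parameter grid", call. = FALSE)
  }
  val_labels <- as_diagnosis(val_labels)
  if (length(unique(val_labels)) < 2) {
    stop("validation split must contain both classes", call. = FALSE)
  }
  best <- NULL
  rows <- list()
  for (ks in sort(kernel_scales)) for (bc in sort(box_constraints)) {
    fit <- train_area_svm(train_x, train_labels, ks, bc)
    pred <- membership_score(fit, as.matrix(val_x)) >= 0.5
    acc <- mean(pred == (val_labels == "ASD"))
    rows[[length(rows) + 1]] <- data.frame(kernel_scale = ks,
                                           box_constraint = bc,
                                           accuracy = acc)
    if (is.null(best) || acc > best$accuracy) {
      best <- list(kernel_scale = ks, box_constraint = bc, accuracy = acc)
    }
  }
  best$results <- do.call(rbind, rows)
  best
}
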