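#' Temporally concatenate subjects for group decomposition
#'
#' Flattens each subject's 4D volume to a timepoints x voxels matrix,
#' optionally variance-normalizes every voxel series within subject (the
#' standard preparation for temporal-concatenation group ICA; voxels with
#' zero variance are left untouched), and row-stacks the subjects.
#'
#' @param volumes list of 4D arrays (x, y, z, t) or of timepoints x voxels
#'   matrices, all on the same voxel grid; a `bold_cohort` is also accepted.
#' @param subset indices of subjects to include (e.g. a matched 20 + 20
#'   subset); default all.
#' @param normalize `"variance"` (default) or `"none"`.
#' @return numeric matrix (total timepoints x voxels) with attributes
#'   `subjects` (indices used) and `timepoints` (frames per subject).
#' @export
temporal_concat <- function(volumes, subset = NULL, normalize = c("variance", "none")) {
  normalize <- match.arg(normalize)
  if (inherits(volumes, "bold_cohort")) {
    if (is.null(volumes$volumes)) {
      stop("cohort has no materialized volumes", call. = FALSE)
    }
    volumes <- volumes$volumes
  }
  if (is.null(subset)) subset <- seq_along(volumes)
  if (!length(subset)) stop("subject subset is empty", call. = FALSE)
  mats <- lapply(volumes[subset], function(v) {
    if (is.matrix(v)) v else vol4d_to_matrix(v)
  })
  nv <- unique(vapply(mats, ncol, integer(1)))
  if (length(nv) != 1) {
    stop("subjects are not on the same voxel grid", call. = FALSE)
  }
  if (normalize == "variance") {
    mats <- lapply(mats, function(m) {
      s <- apply(m, 2, stats::sd)
      s[s == 0] <- 1
      sweep(m, 2, s, "/")
    })
  }
  out <- do.call(rbind, mats)
  attr(out, "subjects") <- subset
  attr(out, "timepoints") <- vapply(mats, nrow, integer(1))
  out
}

#' Fit a group probabilistic ICA model
#'
#' Decomposes a (timepoints x voxels) data matrix into `model_order`
#' statistically independent spatial sources and their mixing time courses
#' under an explicit isotropic Gaussian noise term. The estimation realizes
#' the standard noisy-ICA loop: PCA reduction to `model_order` temporal
#' components with the noise variance initialized from the mean of the
#' discarded eigenvalues, probabilistic-PCA whitening, a fixed-point
#' negentropy-maximizing rotation (symmetric FastICA with the `tanh`
#' contrast), then re-estimation of the noise variance from the residuals of
#' the reconstructed signal, iterated until the noise variance stabilizes.
#'
#' @param data numeric matrix, timepoints x voxels (see [temporal_concat()]).
#' @param model_order number of sources to extract (default 34, the atlas
#'   size; the model order is fixed rather than estimated).
#' @param max_iter maximum fixed-point iterations per ICA rotation.
#' @param tol relative convergence tolerance for both the rotation and the
#'   noise-variance loop.
#' @param seed integer seed for the rotation initialization; fits are
#'   bit-for-bit reproducible given the seed.
#' @param max_noise_iter maximum noise re-estimation cycles.
#' @return an object of class `pica`: `sources` (model_order x voxels, unit
#'   variance rows), `mixing` (timepoints x model_order), `unmixing`
#'   (model_order x timepoints), `noise_variance`, `model_order`,
#'   `iterations`, `converged`, `seed`.
#' @export
fit_group_pica <- function(data, model_order = 34, max_iter = 200,
                           tol = 1e-6, seed = 1, max_noise_iter = 10) {
  x <- as.matrix(data)
  nt <- nrow(x)
  nv <- ncol(x)
  k <- as.integer(model_order)
  if (k < 1 || k > min(nt, nv)) {
    stop("model_order must be between 1 and min(dim(data))", call. = FALSE)
  }
  x <- x - rowMeans(x)
  eg <- eigen(tcrossprod(x) / nv, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  d <- evals[seq_len(k)]
  sigma2 <- if (k < nt) mean(evals[(k + 1):nt]) else 0
  rot <- with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    q
  })
  sym_orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  total_iter <- 0L
  converged <- FALSE
  sources <- NULL
  mixing <- NULL
  whiten <- NULL
  for (cycle in seq_len(max_noise_iter)) {
    gain <- 1 / sqrt(pmax(d - sigma2, 1e-12 * max(d)))
    whiten <- gain * t(u)              # model_order x timepoints
    y <- whiten %*% x                  # whitened sources, k x voxels
    ica_converged <- FALSE
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      wy <- rot %*% y
      g <- tanh(wy)
      gprime <- rowMeans(1 - g^2)
      rot_new <- sym_orth(tcrossprod(g, y) / nv - diag(gprime, k) %*% rot)
      delta <- max(abs(abs(rowSums(rot_new * rot)) - 1))
      rot <- rot_new
      if (delta < tol) {
        ica_converged <- TRUE
        break
      }
    }
    sources <- rot %*% y
    # scale rows to unit variance for a fixed output convention
    sc <- sqrt(rowMeans(sources^2))
    sc[sc == 0] <- 1
    sources <- sources / sc
    mixing <- t(solve(tcrossprod(sources), sources %*% t(x)))
    resid <- x - mixing %*% sources
    df <- max(nt - k, 1)
    sigma2_new <- sum(resid^2) / (df * nv)
    if (abs(sigma2_new - sigma2) <= tol * max(sigma2, 1e-12)) {
      converged <- ica_converged
      sigma2 <- sigma2_new
      break
    }
    sigma2 <- sigma2_new
    converged <- ica_converged
  }
  if (!converged) {
    warning("PICA fixed-point rotation did not fully converge; ",
            "result is flagged (converged = FALSE)")
  }
  structure(list(sources = sources, mixing = mixing,
                 unmixing = rot %*% whiten, noise_variance = sigma2,
                 model_order = k, iterations = total_iter,
                 converged = converged, seed = seed,
                 eigenvalues = evals), class = "pica")
}

#' @export
print.pica <- function(x, ...) {
  cat(sprintf("Group PICA model: %d spatial components, %d x %d data\n",
              x$model_order, nrow(x$mixing), ncol(x$sources)))
  cat(sprintf("  noise variance %.4g, %d fixed-point iterations, %s\n",
              x$noise_variance, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Dual regression: subject-specific time courses and maps
#'
#' Stage 1 regresses each timepoint's voxel vector on the group spatial maps
#' (least squares), giving one time course per component; stage 2 regresses
#' each voxel's series on those time courses, giving subject-specific spatial
#' maps. For data lying exactly in the span of the group maps the two stages
#' reproduce the data (projection idempotence).
#'
#' @param group_sources group spatial maps, components x voxels, or a fitted
#'   `pica` model.
#' @param subject_volume a 4D array or timepoints x voxels matrix on the same
#'   voxel grid.
#' @return an object of class `subject_decomposition`: `timecourses`
#'   (timepoints x components) and `maps` (components x voxels).
#' @export
dual_regression <- function(group_sources, subject_volume) {
  s <- if (inherits(group_sources, "pica")) group_sources$sources
       else as.matrix(group_sources)
  x <- if (is.matrix(subject_volume)) subject_volume
       else vol4d_to_matrix(subject_volume)
  if (ncol(s) != ncol(x)) {
    stop("group maps and subject are not on the same voxel grid",
         call. = FALSE)
  }
  k <- nrow(s)
  gram <- tcrossprod(s)
  qr1 <- qr(gram)
  if (qr1$rank < k) {
    bad <- sort(qr1$pivot[(qr1$rank + 1):k])
    stop(sprintf("group maps are collinear; offending components: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tc <- t(solve(gram, s %*% t(x)))   # timepoints x components
  if (all(tc == 0)) {
    # all-zero subject: both stages are identically zero
    return(structure(list(timecourses = tc,
                          maps = matrix(0, k, ncol(x))),
                     class = "subject_decomposition"))
  }
  gram2 <- crossprod(tc)
  qr2 <- qr(gram2)
  if (qr2$rank < k) {
    bad <- sort(qr2$pivot[(qr2$rank + 1):k])
    stop(sprintf("subject time courses are collinear; offending components: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  maps <- solve(gram2, crossprod(tc, x))  # components x voxels
  structure(list(timecourses = tc, maps = maps),
            class = "subject_decomposition")
}

#' @export
print.subject_decomposition <- function(x, ...) {
  cat(sprintf("Subject decomposition: %d components, %d timepoints, %d voxels\n",
              ncol(x$timecourses), nrow(x$timecourses), ncol(x$maps)))
  invisible(x)
}

#' Permutation test for group differences on component maps
#'
#' For every component, summarizes each subject's map (mean map value over an
#' optional voxel mask), takes the autism-minus-control difference of group
#' means as the test statistic, and computes a two-sided permutation p-value
#' over random label reassignments with the add-one convention
#' `p = (1 + #\{|perm| >= |observed|\}) / (1 + n_permutations)`. Significance
#' is declared at `alpha / K` (Bonferroni over the K components).
#'
#' @param subject_maps list of per-subject map matrices (components x voxels),
#'   e.g. from [dual_regression()].
#' @param labels diagnosis labels ("ASD"/"TD"), one per subject.
#' @param n_permutations number of label permutations (>= 1).
#' @param alpha family-wise significance level before Bonferroni division.
#' @param mask optional voxel indices over which to summarize maps.
#' @param seed integer seed for the permutations.
#' @return data frame with columns `component`, `statistic`, `p_value`,
#'   `significant`.
#' @export
group_difference_test <- function(subject_maps, labels, n_permutations = 999,
                                  alpha = 0.05, mask = NULL, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  labels <- as_diagnosis(labels)
  if (min(table(labels)) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  k <- nrow(subject_maps[[1]])
  summaries <- vapply(subject_maps, function(m) {
    if (is.null(mask)) rowMeans(m) else rowMeans(m[, mask, drop = FALSE])
  }, numeric(k))
  summaries <- matrix(summaries, ncol = k, byrow = TRUE)  # subjects x comps
  stat <- function(lab) {
    colMeans(summaries[lab == "ASD", , drop = FALSE]) -
      colMeans(summaries[lab == "TD", , drop = FALSE])
  }
  observed <- stat(labels)
  exceed <- integer(k)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- stat(sample(labels))
      exceed <- exceed + (abs(perm) >= abs(observed))
    }
  })
  p_value <- (1 + exceed) / (1 + n_permutations)
  data.frame(component = seq_len(k), statistic = observed,
             p_value = p_value, significant = p_value <= alpha / k)
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with kernel standard deviation
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` (in mm, converted to voxels by the
#' voxel size). Kernels are truncated at four standard deviations and
#' renormalized at the volume edges so that constant volumes pass through
#' unchanged. A 4D input is smoothed frame by frame; `fwhm_mm = 0` is the
#' identity.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @param voxel_size_mm voxel edge length(s) in mm, scalar or length 3.
#' @return array of the same shape.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size_mm = 1) {
  if (fwhm_mm < 0) stop("fwhm must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) return(volume)
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(volume)
  if (length(d) == 4) {
    out <- volume
    for (t in seq_len(d[4])) {
      frame <- array(volume[, , , t], d[1:3])
      out[, , , t] <- smooth_gaussian(frame, fwhm_mm, voxel_size_mm)
    }
    return(out)
  }
  if (length(d) != 3) stop("expected a 3D or 4D volume", call. = FALSE)
  kernel_matrix <- function(n, s) {
    if (s <= 0) return(diag(n))
    idx <- seq_len(n)
    km <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    km[abs(outer(idx, idx, "-")) > ceiling(4 * s)] <- 0
    km / rowSums(km)  # edge renormalization: unit row mass everywhere
  }
  out <- volume
  # axis 1
  out <- array(kernel_matrix(d[1], sigma[1]) %*% matrix(out, d[1]), d)
  # axis 2
  out <- aperm(array(kernel_matrix(d[2], sigma[2]) %*%
                       matrix(aperm(out, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  out <- aperm(array(kernel_matrix(d[3], sigma[3]) %*%
                       matrix(aperm(out, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  out
}
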