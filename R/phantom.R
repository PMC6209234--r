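#' Specify a synthetic BOLD phantom cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The phantom
#' emulates the generative structure the decomposition stage assumes: every
#' voxel's BOLD series is a linear mixture of smooth spatial source maps and
#' band-limited time courses plus i.i.d. Gaussian noise. A group difference is
#' injected as a multiplicative in-band spectral-power shift in designated
#' areas of the autism group, and behavioural (ADOS-like) scores are generated
#' with a positive linear dependence on each subject's injected effect.
#'
#' Defaults mirror a typical resting-state acquisition: TR 2 s, 180 frames
#' (about 6 minutes), fluctuations in the 0.01--0.08 Hz band, and a matched
#' 20 + 20 cohort.
#'
#' @param grid_shape integer vector of length 3, voxel grid dimensions.
#' @param n_timepoints number of BOLD frames per subject.
#' @param tr_seconds repetition time in seconds.
#' @param n_areas number of functional areas (default 34, the atlas size).
#' @param affected_areas integer ids of areas carrying the group effect.
#' @param effect_size nonnegative relative in-band power shift: autism-group
#'   power in affected areas is `base_power * (1 + effect_size * severity)`
#'   with per-subject severity drawn uniformly on `[0.5, 1.5]`. Zero makes the
#'   two groups exchangeable by construction.
#' @param noise_sigma standard deviation of the additive voxel noise.
#' @param n_asd,n_td group sizes.
#' @param band low/high edge (Hz) of the fluctuation band.
#' @param base_power total in-band power of an unaffected area time course.
#' @param power_jitter standard deviation of the log-normal per-subject,
#'   per-area power variability (natural within-group heterogeneity; keeps
#'   in-band power non-degenerate under the null).
#' @param behavioral_intercept,behavioral_slope,behavioral_sigma parameters of
#'   the behavioural score model `b0 + b1 * effect_size * severity + noise`,
#'   generated for autism-group subjects only.
#' @param seed integer seed; identical specs give bit-identical cohorts.
#' @return an object of class `phantom_spec`.
#' @seealso [simulate_cohort()], [make_label_volume()]
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12), n_timepoints = 180,
                         tr_seconds = 2, n_areas = 34,
                         affected_areas = integer(0), effect_size = 1,
                         noise_sigma = 0.5, n_asd = 20, n_td = 20,
                         band = c(0.01, 0.08), base_power = 1,
                         power_jitter = 0.15,
                         behavioral_intercept = 6, behavioral_slope = 2,
                         behavioral_sigma = 1, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  }
  if (n_timepoints < 8) stop("n_timepoints must be >= 8", call. = FALSE)
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (n_areas < 1) stop("n_areas must be positive", call. = FALSE)
  affected_areas <- as.integer(affected_areas)
  if (length(affected_areas) &&
      !all(affected_areas %in% seq_len(n_areas))) {
    stop("affected_areas must be a subset of 1..n_areas", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be nonnegative", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative", call. = FALSE)
  if (n_asd < 0 || n_td < 0) stop("group sizes must be nonnegative", call. = FALSE)
  nyq <- 1 / (2 * tr_seconds)
  if (band[1] < 0 || band[2] <= band[1] || band[2] > nyq + 1e-12) {
    stop("band must satisfy 0 <= low < high <= Nyquist", call. = FALSE)
  }
  structure(list(
    grid_shape = grid_shape, n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_areas = as.integer(n_areas),
    affected_areas = sort(unique(affected_areas)), effect_size = effect_size,
    noise_sigma = noise_sigma, n_asd = as.integer(n_asd),
    n_td = as.integer(n_td), band = band, base_power = base_power,
    power_jitter = power_jitter,
    behavioral_intercept = behavioral_intercept,
    behavioral_slope = behavioral_slope,
    behavioral_sigma = behavioral_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("BOLD phantom specification\n")
  cat(sprintf("  grid %s, %d frames, TR %g s\n",
              paste(x$grid_shape, collapse = "x"), x$n_timepoints,
              x$tr_seconds))
  cat(sprintf("  %d areas (%s affected), effect size %g, noise sigma %g\n",
              x$n_areas,
              if (length(x$affected_areas)) length(x$affected_areas) else "none",
              x$effect_size, x$noise_sigma))
  cat(sprintf("  cohort %d ASD + %d TD, seed %d\n", x$n_asd, x$n_td, x$seed))
  invisible(x)
}

#' Build a synthetic atlas label volume
#'
#' Places `n_areas` nonempty, spatially contiguous and pairwise disjoint
#' rectangular regions on the voxel grid; voxel value 0 is background and
#' values `1..n_areas` label the areas. The grid is tiled into blocks and each
#' area occupies the central core of one block; which block hosts which area
#' id is a seeded permutation.
#'
#' @param grid_shape integer vector of length 3.
#' @param n_areas number of areas to place.
#' @param seed integer seed controlling area placement.
#' @return an integer 3D array of labels.
#' @export
make_label_volume <- function(grid_shape, n_areas, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  }
  if (n_areas < 1) stop("n_areas must be positive", call. = FALSE)
  counts <- c(1L, 1L, 1L)
  while (prod(counts) < n_areas) {
    candidates <- which(floor(grid_shape / (counts + 1)) >= 2)
    if (!length(candidates)) {
      stop("grid too small for the requested number of areas", call. = FALSE)
    }
    i <- candidates[which.max((grid_shape / counts)[candidates])]
    counts[i] <- counts[i] + 1L
  }
  block <- floor(grid_shape / counts)
  if (any(block < 2)) {
    stop("grid too small for the requested number of areas", call. = FALSE)
  }
  blocks <- as.matrix(expand.grid(x = seq_len(counts[1]),
                                  y = seq_len(counts[2]),
                                  z = seq_len(counts[3])))
  chosen <- with_seed(seed, sample.int(nrow(blocks), n_areas))
  vol <- array(0L, grid_shape)
  margin <- pmax(0L, floor(block / 4))
  for (a in seq_len(n_areas)) {
    b <- blocks[chosen[a], ]
    start <- (b - 1L) * block + 1L + margin
    end <- b * block - margin
    vol[start[1]:end[1], start[2]:end[2], start[3]:end[3]] <- a
  }
  vol
}

#' Simulate a band-limited BOLD-like time course
#'
#' Synthesizes a zero-mean series directly in the frequency domain: Fourier
#' bins inside `[band_low_hz, band_high_hz]` receive random amplitudes and
#' phases, all other bins are zero, and the series is rescaled so its total
#' (population) variance equals `power`. All spectral power therefore lies in
#' the requested band by construction.
#'
#' @param band_low_hz,band_high_hz band edges in Hz; must satisfy
#'   `0 <= low < high <= 1 / (2 * tr_seconds)`.
#' @param power total in-band power (series variance); 0 returns an all-zero
#'   series.
#' @param n_timepoints series length.
#' @param tr_seconds sampling interval in seconds.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of length `n_timepoints`.
#' @export
simulate_timecourse <- function(band_low_hz, band_high_hz, power,
                                n_timepoints, tr_seconds, seed = NULL) {
  n <- as.integer(n_timepoints)
  nyq <- 1 / (2 * tr_seconds)
  if (band_low_hz < 0 || band_high_hz <= band_low_hz ||
      band_high_hz > nyq + 1e-12) {
    stop("band must satisfy 0 <= low < high <= Nyquist", call. = FALSE)
  }
  if (power < 0) stop("power must be nonnegative", call. = FALSE)
  kmin <- max(1L, as.integer(ceiling(band_low_hz * n * tr_seconds - 1e-9)))
  kmax <- min(as.integer(floor(band_high_hz * n * tr_seconds + 1e-9)),
              n %/% 2L)
  if (kmin > kmax) {
    stop("no Fourier bins inside the requested band at this series length",
         call. = FALSE)
  }
  if (power == 0) return(numeric(n))
  with_seed(seed, {
    k <- kmin:kmax
    amp <- stats::rgamma(length(k), shape = 2, rate = 2) + 0.05
    phase <- stats::runif(length(k), 0, 2 * pi)
    # Nyquist bin (n even) is self-conjugate and must be real
    phase[n %% 2L == 0L & k == n %/% 2L] <- 0
    coef <- complex(modulus = amp, argument = phase)
    f <- complex(real = numeric(n), imaginary = numeric(n))
    f[k + 1L] <- coef
    f[n - k + 1L] <- Conj(coef)
    # restore Nyquist overwrite for even n
    if (n %% 2L == 0L && kmax == n %/% 2L) f[n %/% 2L + 1L] <- coef[length(coef)]
    x <- Re(stats::fft(f, inverse = TRUE)) / n
    x <- x - mean(x)
    x * sqrt(power / mean(x^2))
  })
}

#' Simulate a synthetic BOLD cohort with ground truth
#'
#' Generates a cohort according to a [phantom_spec()]: a seeded label volume,
#' one smooth positive spatial source map per area (a Gaussian profile over
#' the area's voxels, aligned one-to-one with the labels), per-subject
#' band-limited area time courses, and voxel data equal to the
#' map-weighted mixture of the time courses plus Gaussian noise. Subjects of
#' the autism group carry a multiplicative in-band power shift in the affected
#' areas, and a behavioural score correlated with the injected effect.
#'
#' @param spec a [phantom_spec()].
#' @param return_volumes if `FALSE`, skip building the (possibly large) 4D
#'   voxel arrays and return ground truth only; useful for feature-level
#'   simulation studies.
#' @return an object of class `bold_cohort`: a list with `spec`,
#'   `label_volume`, `source_maps` (areas x voxels), `timecourses` (per
#'   subject, timepoints x areas), `labels`, `severity`, `behavioral`
#'   (NA for TD subjects) and `volumes` (per subject 4D arrays, or `NULL`).
#' @export
simulate_cohort <- function(spec, return_volumes = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lab <- make_label_volume(spec$grid_shape, spec$n_areas, seed = spec$seed)
    nv <- prod(spec$grid_shape)
    maps <- matrix(0, spec$n_areas, nv)
    coords <- arrayInd(seq_len(nv), spec$grid_shape)
    for (a in seq_len(spec$n_areas)) {
      vox <- which(lab == a)
      centroid <- colMeans(coords[vox, , drop = FALSE])
      d2 <- rowSums((coords[vox, , drop = FALSE] -
                       matrix(centroid, length(vox), 3, byrow = TRUE))^2)
      width <- max(1, max(d2))
      maps[a, vox] <- exp(-d2 / width)
    }
    n <- spec$n_asd + spec$n_td
    labels <- as_diagnosis(rep(c("ASD", "TD"), c(spec$n_asd, spec$n_td)))
    severity <- stats::runif(n, 0.5, 1.5)
    behavioral_noise <- stats::rnorm(n, 0, spec$behavioral_sigma)
    behavioral <- rep(NA_real_, n)
    timecourses <- vector("list", n)
    volumes <- if (return_volumes) vector("list", n) else NULL
    for (i in seq_len(n)) {
      is_asd <- labels[i] == "ASD"
      tc <- matrix(0, spec$n_timepoints, spec$n_areas)
      for (a in seq_len(spec$n_areas)) {
        shift <- if (is_asd && a %in% spec$affected_areas) {
          1 + spec$effect_size * severity[i]
        } else {
          1
        }
        jitter <- exp(stats::rnorm(1, 0, spec$power_jitter))
        tc[, a] <- simulate_timecourse(spec$band[1], spec$band[2],
                                       spec$base_power * shift * jitter,
                                       spec$n_timepoints, spec$tr_seconds)
      }
      timecourses[[i]] <- tc
      if (is_asd) {
        behavioral[i] <- spec$behavioral_intercept +
          spec$behavioral_slope * spec$effect_size * severity[i] +
          behavioral_noise[i]
      }
      if (return_volumes) {
        x <- tc %*% maps
        if (spec$noise_sigma > 0) {
          x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sigma),
                          nrow(x), ncol(x))
        }
        volumes[[i]] <- matrix_to_vol4d(x, spec$grid_shape)
      }
    }
    structure(list(
      spec = spec, label_volume = lab, source_maps = maps,
      timecourses = timecourses, labels = labels, severity = severity,
      behavioral = behavioral, volumes = volumes
    ), class = "bold_cohort")
  })
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("BOLD phantom cohort: %d ASD + %d TD subjects, %d areas\n",
              x$spec$n_asd, x$spec$n_td, x$spec$n_areas))
  cat(sprintf("  grid %s, %d frames, TR %g s, volumes %s\n",
              paste(x$spec$grid_shape, collapse = "x"),
              x$spec$n_timepoints, x$spec$tr_seconds,
              if (is.null(x$volumes)) "not materialized" else "in memory"))
  invisible(x)
}

#' Ground-truth in-band power per subject and area
#'
#' Population variance of each generated area time course, i.e. the total
#' spectral power the generator injected (all of it in-band by construction).
#' Useful as a direct check that affected areas received the intended shift.
#'
#' @param cohort a `bold_cohort`.
#' @return numeric matrix, subjects x areas.
#' @export
truth_band_power <- function(cohort) {
  stopifnot(inherits(cohort, "bold_cohort"))
  t(vapply(cohort$timecourses,
           function(tc) colMeans(tc^2),
           numeric(cohort$spec$n_areas)))
}

#' Write a phantom cohort to disk in standard formats
#'
#' BOLD volumes and the label volume are written as NIfTI-1 (TR recorded in
#' the time-axis pixdim), subject metadata and ground truth as TSV, and the
#' generating specification as JSON.
#'
#' @param cohort a `bold_cohort` with materialized volumes.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  if (is.null(cohort$volumes)) {
    stop("cohort has no materialized volumes; rerun simulate_cohort() with ",
         "return_volumes = TRUE", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$labels)
  ids <- sprintf("sub-%02d", seq_len(n))
  for (i in seq_len(n)) {
    img <- RNifti::asNifti(cohort$volumes[[i]])
    RNifti::pixdim(img) <- c(1, 1, 1, cohort$spec$tr_seconds)
    RNifti::writeNifti(img, file.path(dir, paste0(ids[i], "_bold.nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(cohort$label_volume),
                     file.path(dir, "labels.nii.gz"))
  write_tsv(data.frame(subject = ids, group = as.character(cohort$labels),
                       severity = cohort$severity,
                       behavioral = cohort$behavioral),
            file.path(dir, "participants.tsv"))
  write_tsv(data.frame(area = seq_len(cohort$spec$n_areas),
                       affected = seq_len(cohort$spec$n_areas) %in%
                         cohort$spec$affected_areas),
            file.path(dir, "truth_areas.tsv"))
  spec <- unclass(cohort$spec)
  write_json(spec, file.path(dir, "phantom_spec.json"))
  invisible(dir)
}
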