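#' Power spectral density of a BOLD time course
#'
#' Default estimator is the full-length one-sided periodogram with mean
#' removal: `S(f_k) = c_k * tr * |X_k|^2 / n` at `f_k = k / (n * tr)`,
#' `k = 1..floor(n/2)`, with `c_k = 2` except at the Nyquist bin of an
#' even-length series. This estimator is exactly invariant under circular
#' time shifts (only Fourier magnitudes enter) and satisfies Parseval's
#' identity: `sum(power) * df` equals the series' population variance.
#' Welch's averaged-segment estimator (Hann window, 50% overlap) is available
#' as an option for lower-variance spectra at the cost of exact shift
#' invariance.
#'
#' @param timecourse numeric vector, at least 8 finite values.
#' @param tr_seconds sampling interval in seconds.
#' @param grid optional increasing vector of frequencies (Hz) onto which the
#'   spectrum is regridded: raw ordinates are averaged within each grid
#'   point's band (band-power aggregation, which also tames periodogram
#'   variance); grids finer than the raw spectrum are linearly interpolated.
#' @param method `"periodogram"` (default) or `"welch"`.
#' @param segment_length Welch segment length (default `length(x) %/% 4`,
#'   minimum 8).
#' @return an object of class `psd`: list with `frequencies` (Hz), `power`
#'   (signal units^2 / Hz) and `tr_seconds`. A constant series yields an
#'   all-zero spectrum with a warning.
#' @export
compute_psd <- function(timecourse, tr_seconds, grid = NULL,
                        method = c("periodogram", "welch"),
                        segment_length = NULL) {
  method <- match.arg(method)
  x <- as.numeric(timecourse)
  n <- length(x)
  if (n < 8) stop("need at least 8 timepoints", call. = FALSE)
  if (!all(is.finite(x))) stop("time course contains non-finite values",
                               call. = FALSE)
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant time course: returning an all-zero spectrum")
    freqs <- (seq_len(n %/% 2)) / (n * tr_seconds)
    out <- list(frequencies = if (is.null(grid)) freqs else grid,
                power = numeric(if (is.null(grid)) length(freqs)
                                else length(grid)),
                tr_seconds = tr_seconds)
    class(out) <- "psd"
    return(out)
  }
  raw <- if (method == "periodogram") {
    periodogram_psd(x, tr_seconds)
  } else {
    welch_psd(x, tr_seconds, segment_length)
  }
  if (!is.null(grid)) {
    if (is.unsorted(grid, strictly = TRUE) || any(grid < 0)) {
      stop("grid must be strictly increasing and nonnegative", call. = FALSE)
    }
    raw <- list(frequencies = grid,
                power = regrid_psd(raw$frequencies, raw$power, grid),
                tr_seconds = tr_seconds)
  }
  class(raw) <- "psd"
  raw
}

# Map a raw spectrum onto a coarser common grid. Each grid point owns the
# half-open band up to it (edges midway to its neighbours at the boundary);
# raw ordinates falling inside are averaged, which reduces periodogram
# variance the way band-power features do. Grids finer than the raw spectrum
# fall back to linear interpolation (constant extrapolation at the ends).
regrid_psd <- function(freqs, power, grid) {
  edges <- c(0, grid[-length(grid)] + diff(grid) / 2,
             grid[length(grid)] + diff(grid)[length(grid) - 1] / 2)
  if (length(grid) == 1) edges <- c(0, Inf)
  bin <- findInterval(freqs, edges, left.open = TRUE, rightmost.closed = FALSE)
  out <- numeric(length(grid))
  for (j in seq_along(grid)) {
    inside <- bin == j
    out[j] <- if (any(inside)) {
      mean(power[inside])
    } else {
      stats::approx(freqs, power, xout = grid[j], rule = 2)$y
    }
  }
  pmax(out, 0)
}

periodogram_psd <- function(x, tr) {
  n <- length(x)
  xm <- x - mean(x)
  f <- stats::fft(xm)
  k <- seq_len(n %/% 2)
  scale <- rep(2, length(k))
  if (n %% 2 == 0) scale[length(k)] <- 1
  list(frequencies = k / (n * tr),
       power = scale * tr * Mod(f[k + 1])^2 / n,
       tr_seconds = tr)
}

welch_psd <- function(x, tr, segment_length = NULL) {
  n <- length(x)
  if (is.null(segment_length)) segment_length <- max(8L, n %/% 4L)
  m <- as.integer(segment_length)
  if (m < 8 || m > n) stop("segment_length must be in [8, n]", call. = FALSE)
  step <- max(1L, m %/% 2L)
  starts <- seq(1L, n - m + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))  # Hann
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + m - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- periodogram_psd(seg, tr)$power / mean(w^2)
    acc <- if (is.null(acc)) p else acc + p
  }
  list(frequencies = seq_len(m %/% 2) / (m * tr),
       power = acc / length(starts), tr_seconds = tr)
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("PSD: %d bins, %.4g-%.4g Hz, total power %.4g\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              sum(x$power) * mean(diff(c(0, x$frequencies)))))
  invisible(x)
}

#' @export
plot.psd <- function(x, ...) {
  plot(x$frequencies, x$power, type = "h", xlab = "frequency (Hz)",
       ylab = "power (units^2/Hz)", ...)
  invisible(x)
}

#' Common frequency grid for a cohort
#'
#' Equally spaced bin centers `f_max / n_bins, ..., f_max` where `f_max`
#' defaults to the smallest Nyquist frequency across the repetition times
#' supplied, so that cohorts acquired at different TRs (e.g. 2 s and 3 s) are
#' represented on one grid.
#'
#' @param tr_seconds vector of repetition times present in the cohort.
#' @param n_bins number of frequency bins (default 32).
#' @param f_max optional upper frequency; default `min(1 / (2 * tr))`.
#' @return increasing numeric vector of length `n_bins`.
#' @export
psd_grid <- function(tr_seconds, n_bins = 32, f_max = NULL) {
  if (is.null(f_max)) f_max <- 1 / (2 * max(tr_seconds))
  seq(f_max / n_bins, f_max, length.out = n_bins)
}

#' Per-area PSD feature vectors for one subject
#'
#' For each atlas area, takes the subject time course of the spatial map
#' matched to that area and computes its PSD on the pipeline's common
#' frequency grid.
#'
#' @param subject_decomposition a [dual_regression()] result.
#' @param assignment a [match_components()] result covering all registry
#'   areas.
#' @param registry the [build_registry()] used for matching.
#' @param tr_seconds the subject's repetition time.
#' @param grid common frequency grid (see [psd_grid()]).
#' @param ... passed to [compute_psd()] (estimator options).
#' @return numeric matrix, areas x frequency bins, with the grid stored in
#'   the `"frequencies"` attribute and area ids as row names.
#' @export
extract_features <- function(subject_decomposition, assignment, registry,
                             tr_seconds, grid = psd_grid(tr_seconds), ...) {
  stopifnot(inherits(registry, "atlas_registry"))
  tc <- subject_decomposition$timecourses
  ids <- vapply(registry$components, `[[`, numeric(1), "id")
  out <- matrix(NA_real_, length(ids), length(grid),
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    row <- assignment[assignment$area_id == ids[i], , drop = FALSE]
    if (nrow(row) != 1 || is.na(row$map_index)) {
      stop(sprintf("no matched map for atlas area %d ('%s')", ids[i],
                   registry$components[[i]]$name), call. = FALSE)
    }
    psd <- suppressWarnings(
      compute_psd(tc[, row$map_index], tr_seconds, grid = grid, ...)
    )
    out[i, ] <- psd$power
  }
  attr(out, "frequencies") <- grid
  out
}

#' Feature array for a whole phantom cohort from ground-truth time courses
#'
#' Bypasses the decomposition stage and computes per-area PSD features
#' directly from the generator's area time courses. This is the fast path for
#' classifier-level simulation studies where the decomposition is not under
#' test.
#'
#' @param cohort a `bold_cohort`.
#' @param n_bins number of frequency bins.
#' @param grid optional explicit frequency grid.
#' @return numeric array, subjects x areas x bins, with attributes
#'   `frequencies` and `labels`.
#' @export
features_from_truth <- function(cohort, n_bins = 32, grid = NULL) {
  stopifnot(inherits(cohort, "bold_cohort"))
  tr <- cohort$spec$tr_seconds
  if (is.null(grid)) grid <- psd_grid(tr, n_bins)
  n <- length(cohort$timecourses)
  a <- cohort$spec$n_areas
  out <- array(NA_real_, c(n, a, length(grid)))
  for (i in seq_len(n)) {
    for (j in seq_len(a)) {
      out[i, j, ] <- suppressWarnings(
        compute_psd(cohort$timecourses[[i]][, j], tr, grid = grid)$power
      )
    }
  }
  attr(out, "frequencies") <- grid
  attr(out, "labels") <- cohort$labels
  out
}
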