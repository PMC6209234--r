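#' Run the decomposition-to-features pipeline on a cohort
#'
#' Convenience wrapper binding the published stage order: temporal
#' concatenation of the (optionally subset) cohort, group probabilistic ICA,
#' dual regression per subject, correlation matching of the group maps to
#' the atlas registry, and per-area PSD feature extraction on the common
#' frequency grid.
#'
#' @param cohort a `bold_cohort` with materialized volumes, or a list of 4D
#'   arrays together with `tr_seconds` and `registry`.
#' @param registry atlas registry; default built from the cohort's label
#'   volume with generic phantom metadata.
#' @param model_order group ICA model order; default the registry size.
#' @param group_subset subjects used for the group decomposition (default
#'   all; the reference pipeline used a matched 20 + 20 subset).
#' @param n_bins frequency bins of the common PSD grid.
#' @param tr_seconds repetition time; taken from the cohort spec when absent.
#' @param seed seed for the group decomposition.
#' @param ... further arguments to [fit_group_pica()].
#' @return list with `features` (subjects x areas x bins array, labels
#'   attached when known), `pica`, `assignment`, `registry` and `grid`.
#' @export
pipeline_features <- function(cohort, registry = NULL, model_order = NULL,
                              group_subset = NULL, n_bins = 32,
                              tr_seconds = NULL, seed = 1, ...) {
  if (inherits(cohort, "bold_cohort")) {
    volumes <- cohort$volumes
    if (is.null(volumes)) stop("cohort has no materialized volumes",
                               call. = FALSE)
    if (is.null(tr_seconds)) tr_seconds <- cohort$spec$tr_seconds
    if (is.null(registry)) {
      registry <- build_registry(cohort$label_volume,
                                 phantom_atlas_table(cohort$spec$n_areas))
    }
    labels <- cohort$labels
  } else {
    volumes <- cohort
    labels <- NULL
    if (is.null(registry) || is.null(tr_seconds)) {
      stop("registry and tr_seconds are required for a plain volume list",
           call. = FALSE)
    }
  }
  if (is.null(model_order)) model_order <- length(registry)
  data <- temporal_concat(volumes, subset = group_subset)
  pica <- fit_group_pica(data, model_order = model_order, seed = seed, ...)
  assignment <- match_components(pica$sources, registry)
  grid <- psd_grid(tr_seconds, n_bins)
  feats <- NULL
  for (i in seq_along(volumes)) {
    sdec <- dual_regression(pica, volumes[[i]])
    f <- extract_features(sdec, assignment, registry, tr_seconds, grid)
    if (is.null(feats)) {
      feats <- array(NA_real_, c(length(volumes), nrow(f), ncol(f)))
    }
    feats[i, , ] <- f
  }
  attr(feats, "frequencies") <- grid
  if (!is.null(labels)) attr(feats, "labels") <- labels
  list(features = feats, pica = pica, assignment = assignment,
       registry = registry, grid = grid)
}
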