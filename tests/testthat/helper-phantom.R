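# Shared fixture builders. Everything is generated in code at test time;
# sizes are deliberately small so the whole suite stays fast.

# Feature-level cohort: ground-truth time courses only (no voxel volumes).
feature_cohort <- function(seed, effect_size = 2, n_areas = 10,
                           affected = c(1, 2, 3), n_asd = 20, n_td = 20,
                           n_timepoints = 160, n_bins = 8) {
  spec <- phantom_spec(grid_shape = c(12, 12, 6), n_timepoints = n_timepoints,
                       n_areas = n_areas, affected_areas = affected,
                       effect_size = effect_size, noise_sigma = 0.5,
                       n_asd = n_asd, n_td = n_td, seed = seed)
  cohort <- simulate_cohort(spec, return_volumes = FALSE)
  list(features = features_from_truth(cohort, n_bins = n_bins),
       labels = cohort$labels, cohort = cohort)
}

# Volume-level cohort for decomposition tests.
volume_cohort <- function(seed, n_areas = 6, n_asd = 4, n_td = 4,
                          grid = c(12, 12, 6), n_timepoints = 60,
                          noise_sigma = 0.5, effect_size = 0,
                          affected = integer(0)) {
  spec <- phantom_spec(grid_shape = grid, n_timepoints = n_timepoints,
                       n_areas = n_areas, affected_areas = affected,
                       effect_size = effect_size, noise_sigma = noise_sigma,
                       n_asd = n_asd, n_td = n_td, seed = seed)
  simulate_cohort(spec)
}

# O(n^2) concordance-probability oracle for the AUC (ties count one half).
auc_concordance_oracle <- function(scores, labels) {
  pos <- scores[labels == "ASD"]
  neg <- scores[labels != "ASD"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
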