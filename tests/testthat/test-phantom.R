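test_that("label volumes have the requested nonempty disjoint areas", {
  vol <- make_label_volume(c(20, 20, 10), 4, seed = 1)
  expect_setequal(sort(unique(as.vector(vol))), 0:4)
  for (a in 1:4) expect_gt(sum(vol == a), 0)

  vol34 <- make_label_volume(c(30, 30, 20), 34, seed = 2)
  expect_equal(sort(unique(as.vector(vol34)))[-1], 1:34)

  expect_identical(make_label_volume(c(20, 20, 10), 4, seed = 1), vol)
  expect_false(identical(make_label_volume(c(20, 20, 10), 4, seed = 9), vol))
  expect_error(make_label_volume(c(3, 3, 2), 34), "too small")
})

test_that("label areas are spatially contiguous boxes", {
  vol <- make_label_volume(c(18, 14, 9), 5, seed = 3)
  for (a in 1:5) {
    idx <- which(vol == a, arr.ind = TRUE)
    ranges <- apply(idx, 2, function(v) diff(range(v)) + 1)
    expect_equal(nrow(idx), prod(ranges))  # filled bounding box
  }
})

test_that("simulated time courses are band-limited with the requested power", {
  x <- simulate_timecourse(0.01, 0.08, 1, 120, 2, seed = 4)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(mean(x^2), 1, tolerance = 1e-10)
  # independent oracle: stats::spec.pgram periodogram, in-band fraction
  sp <- stats::spec.pgram(stats::ts(x, deltat = 2), taper = 0, detrend = FALSE,
                          plot = FALSE)
  in_band <- sp$freq >= 0.01 - 1e-9 & sp$freq <= 0.08 + 1e-9
  expect_gte(sum(sp$spec[in_band]) / sum(sp$spec), 0.9)

  expect_identical(simulate_timecourse(0.01, 0.08, 2, 64, 2, seed = 5),
                   simulate_timecourse(0.01, 0.08, 2, 64, 2, seed = 5))
  expect_equal(simulate_timecourse(0.01, 0.08, 0, 64, 2, seed = 5),
               numeric(64))
  expect_error(simulate_timecourse(0.1, 0.3, 1, 64, 2), "Nyquist")
})

test_that("cohort voxel data are an exact source mixture when noiseless", {
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_timepoints = 40,
                       n_areas = 3, noise_sigma = 0, n_asd = 1, n_td = 1,
                       seed = 6)
  cohort <- simulate_cohort(spec)
  for (i in 1:2) {
    x <- asdcad:::vol4d_to_matrix(cohort$volumes[[i]])
    expect_equal(x, cohort$timecourses[[i]] %*% cohort$source_maps,
                 tolerance = 1e-12)
  }
  # single-area check: every in-area voxel series proportional to its source
  spec1 <- phantom_spec(grid_shape = c(8, 8, 4), n_timepoints = 40,
                        n_areas = 1, noise_sigma = 0, n_asd = 1, n_td = 0,
                        seed = 7)
  c1 <- simulate_cohort(spec1)
  x <- asdcad:::vol4d_to_matrix(c1$volumes[[1]])
  vox <- which(c1$label_volume == 1)
  tc <- c1$timecourses[[1]][, 1]
  for (v in vox[1:5]) {
    expect_equal(stats::cor(x[, v], tc), 1, tolerance = 1e-10)
  }
})

test_that("cohorts are bit-identical under a repeated seed", {
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_timepoints = 40,
                       n_areas = 4, affected_areas = 1, effect_size = 2,
                       n_asd = 2, n_td = 2, seed = 11)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$timecourses, b$timecourses)
  expect_identical(a$behavioral, b$behavioral)
})

test_that("a large injected effect strictly orders group mean in-band power", {
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_timepoints = 80,
                       n_areas = 4, affected_areas = c(1, 2),
                       effect_size = 3, noise_sigma = 0.1,
                       n_asd = 10, n_td = 10, seed = 12)
  cohort <- simulate_cohort(spec, return_volumes = FALSE)
  bp <- truth_band_power(cohort)
  asd <- cohort$labels == "ASD"
  for (a in 1:2) {
    expect_gt(min(bp[asd, a]), max(bp[!asd, a]))
  }
  # unaffected areas must not separate
  for (a in 3:4) {
    expect_lt(abs(mean(bp[asd, a]) - mean(bp[!asd, a])), 0.5)
  }
})

test_that("groups are exchangeable when the effect size is zero", {
  nonsig <- 0
  for (r in 1:50) {
    spec <- phantom_spec(grid_shape = c(8, 8, 4), n_timepoints = 60,
                         n_areas = 2, affected_areas = 1, effect_size = 0,
                         n_asd = 10, n_td = 10, seed = 7000 + r)
    cohort <- simulate_cohort(spec, return_volumes = FALSE)
    bp <- truth_band_power(cohort)
    p <- stats::t.test(bp[cohort$labels == "ASD", 1],
                       bp[cohort$labels == "TD", 1])$p.value
    nonsig <- nonsig + (p > 0.01)
  }
  expect_gte(nonsig, 45)
})

test_that("behavioural scores track injected severity for affected subjects", {
  spec <- phantom_spec(grid_shape = c(8, 8, 4), n_timepoints = 40,
                       n_areas = 2, affected_areas = 1, effect_size = 2,
                       n_asd = 40, n_td = 5, seed = 13)
  cohort <- simulate_cohort(spec, return_volumes = FALSE)
  asd <- cohort$labels == "ASD"
  expect_true(all(is.na(cohort$behavioral[!asd])))
  expect_gt(stats::cor(cohort$behavioral[asd], cohort$severity[asd]), 0.5)
})

test_that("cohorts round-trip to NIfTI and TSV on disk", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(grid_shape = c(8, 8, 4), n_timepoints = 20,
                       n_areas = 2, n_asd = 2, n_td = 1, seed = 14)
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, dir)
  img <- RNifti::readNifti(file.path(dir, "sub-01_bold.nii.gz"))
  expect_equal(dim(img), c(8, 8, 4, 20))
  expect_equal(RNifti::pixdim(img)[4], 2)
  expect_equal(as.vector(img), as.vector(cohort$volumes[[1]]),
               tolerance = 1e-6)
  parts <- read.delim(file.path(dir, "participants.tsv"))
  expect_equal(parts$group, c("ASD", "ASD", "TD"))
  lab <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  expect_equal(as.vector(lab), as.vector(cohort$label_volume))
})

test_that("phantom specifications validate their invariants", {
  expect_error(phantom_spec(affected_areas = 99, n_areas = 10), "subset")
  expect_error(phantom_spec(effect_size = -1), "nonnegative")
  expect_error(phantom_spec(band = c(0.1, 0.4), tr_seconds = 2), "Nyquist")
  expect_error(phantom_spec(grid_shape = c(4, 4)), "3 positive")
})
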