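test_that("temporal concatenation stacks subjects in order", {
  vols <- list(array(stats::rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)),
               array(stats::rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)))
  x <- temporal_concat(vols, normalize = "none")
  expect_equal(dim(x), c(20, 32))
  expect_equal(x[1:10, ], asdcad:::vol4d_to_matrix(vols[[1]]))

  xn <- temporal_concat(vols)
  expect_equal(apply(xn[1:10, ], 2, stats::sd), rep(1, 32), tolerance = 1e-12)

  expect_error(temporal_concat(vols, subset = integer(0)), "empty")
  vols[[2]] <- array(0, c(3, 4, 2, 10))
  expect_error(temporal_concat(vols), "grid")
})

test_that("a 20+20 subset is accepted and kept in the given order", {
  cohort <- volume_cohort(21, n_areas = 2, n_asd = 2, n_td = 2,
                          grid = c(6, 6, 3), n_timepoints = 12)
  x <- temporal_concat(cohort$volumes, subset = c(1, 2, 3, 4))
  expect_equal(attr(x, "subjects"), c(1, 2, 3, 4))
  expect_equal(nrow(x), 48)
})

test_that("group PICA returns the requested number of components", {
  x <- matrix(stats::rnorm(60 * 300), 60, 300)
  fit <- suppressWarnings(fit_group_pica(x, model_order = 5, seed = 1,
                                         max_iter = 50))
  expect_s3_class(fit, "pica")
  expect_equal(nrow(fit$sources), 5)
  expect_equal(dim(fit$mixing), c(60, 5))
  expect_error(fit_group_pica(x, model_order = 100), "model_order")
})

test_that("group PICA is reproducible bit for bit under a fixed seed", {
  x <- matrix(stats::rnorm(40 * 500), 40, 500)
  a <- suppressWarnings(fit_group_pica(x, model_order = 3, seed = 7))
  b <- suppressWarnings(fit_group_pica(x, model_order = 3, seed = 7))
  expect_identical(a$sources, b$sources)
  expect_identical(a$noise_variance, b$noise_variance)
})

test_that("PICA recovers noiseless super-Gaussian sources", {
  set.seed(5)
  s <- matrix(stats::rexp(4 * 2000) - stats::rexp(4 * 2000), 4, 2000)
  a <- matrix(stats::rnorm(60 * 4), 60, 4)
  fit <- fit_group_pica(a %*% s, model_order = 4, seed = 2)
  cc <- abs(stats::cor(t(fit$sources), t(s)))
  expect_gte(mean(apply(cc, 2, max)), 0.95)
  expect_lt(fit$noise_variance, 1e-10)
})

test_that("PICA noise variance matches the generator on pure Gaussian noise", {
  set.seed(6)
  sigma <- 2
  x <- matrix(stats::rnorm(50 * 2000, sd = sigma), 50, 2000)
  fit <- suppressWarnings(fit_group_pica(x, model_order = 4, seed = 2,
                                         max_iter = 50))
  expect_lt(abs(fit$noise_variance - sigma^2) / sigma^2, 0.1)
})

test_that("dual regression recovers exact time courses on in-span data", {
  set.seed(8)
  s <- matrix(stats::rnorm(3 * 500), 3, 500)
  a <- matrix(stats::rnorm(40 * 3), 40, 3)
  sdec <- dual_regression(s, a %*% s)
  expect_equal(sdec$timecourses, a, tolerance = 1e-10)
  expect_equal(sdec$maps, s, tolerance = 1e-10)

  # projection idempotence: stage outputs reproduce in-span data exactly
  expect_equal(sdec$timecourses %*% sdec$maps, a %*% s, tolerance = 1e-10)
})

test_that("dual regression handles degenerate inputs as specified", {
  set.seed(9)
  s <- matrix(stats::rnorm(2 * 200), 2, 200)
  zero <- matrix(0, 30, 200)
  sdec <- dual_regression(s, zero)
  expect_equal(sdec$timecourses, matrix(0, 30, 2))
  expect_equal(sdec$maps, matrix(0, 2, 200))

  # orthonormal maps: stage 1 equals plain projection (inner products)
  q <- qr.Q(qr(matrix(stats::rnorm(200 * 2), 200, 2)))
  x <- matrix(stats::rnorm(15 * 200), 15, 200)
  sdec2 <- dual_regression(t(q), x)
  expect_equal(sdec2$timecourses, x %*% q, tolerance = 1e-10)

  # collinear maps are named in the error
  s_bad <- rbind(s, s[1, ])
  expect_error(dual_regression(s_bad, x), "collinear")
  expect_error(dual_regression(s, matrix(0, 10, 100)), "grid")
})

test_that("group-difference permutation p-values behave at the boundaries", {
  maps <- replicate(8, matrix(stats::rnorm(3 * 50), 3, 50), simplify = FALSE)
  labels <- rep(c("ASD", "TD"), each = 4)
  # identical maps in both groups: statistic 0 always, p = 1
  same <- replicate(8, maps[[1]], simplify = FALSE)
  res <- group_difference_test(same, labels, n_permutations = 99, seed = 1)
  expect_equal(res$p_value, rep(1, 3))
  # K = 1: Bonferroni threshold equals alpha
  one <- lapply(maps, function(m) m[1, , drop = FALSE])
  res1 <- group_difference_test(one, labels, n_permutations = 99,
                                alpha = 0.05, seed = 1)
  expect_equal(res1$significant, res1$p_value <= 0.05)
  expect_error(group_difference_test(maps, labels, n_permutations = 0),
               "n_permutations")
})

test_that("the Bonferroni-corrected test controls family-wise error", {
  fwe <- 0
  for (r in 1:50) {
    set.seed(3000 + r)
    maps <- replicate(12, matrix(stats::rnorm(5 * 40), 5, 40),
                      simplify = FALSE)
    labels <- rep(c("ASD", "TD"), each = 6)
    res <- group_difference_test(maps, labels, n_permutations = 199,
                                 alpha = 0.05, seed = r)
    fwe <- fwe + any(res$significant)
  }
  expect_lte(fwe, 5)  # alpha = 0.05 over 50 runs, generous margin
})

test_that("Gaussian smoothing has the stated kernel width and identities", {
  vol <- array(stats::rnorm(10 * 10 * 6), c(10, 10, 6))
  expect_identical(smooth_gaussian(vol, 0), vol)
  expect_error(smooth_gaussian(vol, -1), "nonnegative")

  # fwhm 2 mm at 1 mm voxels: sigma = 2 / (2 sqrt(2 ln 2)) = 0.8493 voxels
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 0.8493218, tolerance = 1e-6)
  # impulse response second moment matches sigma^2 (interior voxel)
  imp <- array(0, c(21, 21, 11))
  imp[11, 11, 6] <- 1
  sm <- smooth_gaussian(imp, 2, 1)
  marg <- apply(sm, 1, sum)
  expect_equal(sum(marg * (seq_len(21) - 11)^2) / sum(marg), sigma^2,
               tolerance = 1e-3)

  const <- array(3.5, c(8, 8, 4))
  expect_equal(smooth_gaussian(const, 2), const, tolerance = 1e-12)

  vol4 <- array(stats::rnorm(6 * 6 * 3 * 4), c(6, 6, 3, 4))
  sm4 <- smooth_gaussian(vol4, 2)
  expect_equal(sm4[, , , 2], smooth_gaussian(vol4[, , , 2], 2))
})
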