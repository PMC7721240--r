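test_that("truth patterns have the stated structure", {
  g <- volume_grid(c(10, 10, 10))
  expect_length(make_truth("null", g)$support, 0)
  expect_length(make_truth("localized_strong", g, support_radius_vox = 0)$support, 1)
  tr <- make_truth("diffuse_weak", g, diffuse_fraction = 0.3)
  expect_equal(length(tr$support), 300, tolerance = 0.01)
  expect_true(all(tr$rho_map[tr$support] == 0.15))
  expect_error(make_truth("localized_strong", g, rho_strong = 1), "rho")
})

test_that("cohorts are bit-identical under the same seed and differ otherwise", {
  tr <- make_truth("localized_strong", tiny_grid(), support_radius_vox = 1)
  a <- simulate_cohort(12, tr, hcp_covariates(), seed = 5)
  b <- simulate_cohort(12, tr, hcp_covariates(), seed = 5)
  c <- simulate_cohort(12, tr, hcp_covariates(), seed = 6)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_false(identical(a$X, c$X))
})

test_that("identity covariate matrix gives uncorrelated covariates", {
  cov0 <- covariate_structure(diag(3))
  cv <- simulate_covariates(100000, cov0, seed = 9)
  cc <- stats::cor(cbind(cv$age, cv$fd, cv$behavior))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.01)
})

test_that("embedded voxel-behavior correlations are recovered at n = 10,000", {
  # the sampling SE of a correlation at n = 10,000 is ~0.01, so over a few
  # hundred support voxels the mean deviation should be well below 0.01 and
  # the worst single voxel below 4.5 SE
  g <- volume_grid(c(8, 8, 8))
  for (pattern in c("localized_strong", "diffuse_weak")) {
    tr <- make_truth(pattern, g)
    ch <- simulate_cohort(10000, tr, dallas_covariates(), seed = 77)
    rho <- vectorize(tr$rho_map, ch$mask)
    emp <- voxelwise_corr(ch$X, ch$y)$values
    dev <- emp[tr$support] - rho[tr$support]
    expect_lt(abs(mean(dev)), 0.01, label = paste("mean recovery,", pattern))
    expect_lt(max(abs(dev)), 0.045, label = paste("worst voxel,", pattern))
  }
})

test_that("behavior clipping barely distorts the embedded correlation", {
  # correlation against the clipped score vs the latent it was embedded on
  g <- volume_grid(c(4, 4, 4))
  tr <- make_truth("localized_strong", g, support_radius_vox = 1)
  cv <- simulate_covariates(20000, dallas_covariates(),
                            derive_seed(31, "covariates"))
  ch <- simulate_cohort(20000, tr, dallas_covariates(), seed = 31)
  v <- tr$support[1]
  r_clipped <- stats::cor(ch$X[, v], ch$y)
  r_latent <- stats::cor(ch$X[, v], cv$behavior_latent)
  expect_lt(abs(r_clipped - r_latent), 0.02)
})

test_that("null cohorts carry no voxel-behavior correlation", {
  tr <- make_truth("null", volume_grid(c(5, 5, 4)))
  ch <- simulate_cohort(50000, tr, hcp_covariates(), seed = 13)
  emp <- voxelwise_corr(ch$X, ch$y)$values
  expect_lt(max(abs(emp)), 0.02)
})

test_that("dallas preset is balanced over its four age brackets", {
  ch <- simulate_preset_cohort("dallas_like", make_truth("null", tiny_grid()),
                               seed = 3)
  expect_equal(nrow(ch$X), 171)
  counts <- table(ch$strata)
  expect_equal(length(counts), 4)
  expect_true(all(counts >= 42))   # every Dallas schedule entry is feasible
  expect_true(all(ch$C[, "age"] >= 20 & ch$C[, "age"] <= 94))
})

test_that("cohorts round-trip through disk within float32 precision", {
  tr <- make_truth("localized_strong", tiny_grid(), support_radius_vox = 1)
  ch <- simulate_cohort(10, tr, hcp_covariates(), seed = 21)
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  files <- list.files(d)
  expect_length(grep("_contrast[.]nii[.]gz$", files), 10)
  expect_true(all(c("mask.nii.gz", "participants.csv", "truth_rho.nii.gz",
                    "config.yaml") %in% files))
  back <- read_cohort(d)
  expect_equal(back$X, ch$X, tolerance = 1e-6)
  expect_equal(back$y, ch$y, tolerance = 1e-7)
  expect_equal(vectorize(back$truth$rho_map, back$mask),
               vectorize(tr$rho_map, ch$mask), tolerance = 1e-7)
})

test_that("voxels NaN in any participant are dropped from the analysis mask", {
  tr <- make_truth("null", tiny_grid())
  ch <- simulate_cohort(5, tr, hcp_covariates(), seed = 8)
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  # poke a NaN into one participant's volume
  f <- file.path(d, "sub-0003_contrast.nii.gz")
  v <- load_volume(f)
  v$data[2, 2, 2] <- NaN
  save_volume(v$data, v$grid, f)
  back <- read_cohort(d)
  expect_equal(back$mask$n_voxels, ch$mask$n_voxels - 1L)
  expect_false(back$mask$in_mask[2, 2, 2])
  expect_true(all(is.finite(back$X)))
})

test_that("age loading adds covariate signal that residualization removes", {
  g <- volume_grid(c(4, 4, 4))
  tr <- make_truth("null", g)
  loading <- rep(0.6, prod(g$shape))
  ch <- simulate_cohort(4000, tr, dallas_covariates(), seed = 99,
                        age_loading = loading)
  raw_r <- stats::cor(ch$X[, 1], ch$C[, "age"])
  expect_gt(raw_r, 0.5)
  Xr <- residualize(ch$X[, 1], ch$C)
  expect_lt(abs(stats::cor(Xr, ch$C[, "age"])), 0.05)
})
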