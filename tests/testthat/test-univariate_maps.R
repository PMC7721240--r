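test_that("residualize returns OLS residuals orthogonal to covariates", {
  set.seed(1)
  n <- 30
  C <- cbind(rnorm(n), rnorm(n))
  v <- rnorm(n)
  res <- residualize(v, C)
  expect_lt(abs(sum(res * C[, 1])) / sqrt(sum(res^2) * sum(C[, 1]^2)), 1e-8)
  expect_lt(abs(sum(res * C[, 2])) / sqrt(sum(res^2) * sum(C[, 2]^2)), 1e-8)
  expect_lt(abs(mean(res)), 1e-10)
  # matrix input residualizes each column
  M <- matrix(rnorm(n * 5), n, 5)
  resM <- residualize(M, C)
  expect_equal(dim(resM), dim(M))
  # projection idempotence: already-orthogonal centered input is unchanged
  again <- residualize(res, C)
  expect_equal(again, res, tolerance = 1e-10)
  # exact linear function of a covariate residualizes to ~0
  expect_lt(max(abs(residualize(2 * C[, 1], C))), 1e-10)
})

test_that("residualize rejects degenerate designs", {
  expect_error(residualize(rnorm(10), cbind(rep(1, 10))), "rank-deficient")
  expect_error(residualize(rnorm(3), cbind(rnorm(3), rnorm(3))), "participants")
})

test_that("residualize-then-correlate equals the partial correlation formula", {
  set.seed(2)
  for (i in 1:10) {
    n <- 25
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    r_resid <- stats::cor(residualize(x, cbind(z)), residualize(y, cbind(z)))
    R <- stats::cor(cbind(x, y, z))
    r_partial <- (R[1, 2] - R[1, 3] * R[2, 3]) /
      sqrt((1 - R[1, 3]^2) * (1 - R[2, 3]^2))
    expect_equal(r_resid, r_partial, tolerance = 1e-10)
  }
})

test_that("voxelwise_corr matches the sum-formula oracle and handles edge voxels", {
  set.seed(3)
  n <- 6
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  X[, 3] <- y          # perfect positive
  X[, 4] <- -y         # perfect negative
  m <- voxelwise_corr(X, y)
  # brute-force sum formula
  oracle <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  for (v in 1:2) expect_equal(m$values[v], oracle(X[, v], y), tolerance = 1e-12)
  expect_equal(m$values[3], 1)
  expect_equal(m$values[4], -1)
  # zero-variance voxel flagged with r = 0
  X[, 2] <- 5
  m2 <- voxelwise_corr(X, y)
  expect_equal(m2$values[2], 0)
  expect_true(m2$flagged[2])
  expect_error(voxelwise_corr(X, rep(1, n)), "constant")
})

test_that("voxelwise_corr is invariant to affine rescaling", {
  set.seed(4)
  X <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  a <- voxelwise_corr(X, y)$values
  b <- voxelwise_corr(X * 3.7 + 2, 10 - 0 * y + 2 * y)$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("r_to_t applies the exact transform with capping and monotonicity", {
  mk <- function(r, n = 20) stat_map(r, "r", n = n)
  expect_equal(r_to_t(mk(0), n = 20, q_covariates = 2)$values, 0)
  expect_equal(r_to_t(mk(0.5), n = 20, q_covariates = 0)$values,
               0.5 * sqrt(18 / 0.75))
  expect_equal(r_to_t(mk(0.5), n = 20, q_covariates = 2)$df, 16)
  expect_equal(r_to_t(mk(0.5), n = 20, q_covariates = 2)$values,
               0.5 * sqrt(16 / 0.75))
  rs <- seq(-0.95, 0.95, by = 0.05)
  ts <- r_to_t(mk(rs), n = 20)$values
  expect_true(all(diff(ts) > 0))
  expect_equal(r_to_t(mk(1), n = 20)$values, 1e6)
  expect_equal(r_to_t(mk(-1), n = 20)$values, -1e6)
  expect_error(r_to_t(mk(0.2), n = 4, q_covariates = 2), "df")
})

test_that("group_ttest matches t.test and handles degenerate voxels", {
  set.seed(5)
  X <- matrix(rnorm(5 * 3, mean = 0.5), 5, 3)
  m <- group_ttest(X)
  for (v in 1:3) {
    expect_equal(m$values[v], unname(stats::t.test(X[, v])$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(m$df, 4)
  # symmetric around zero -> t = 0
  Xs <- cbind(c(-2, -1, 0, 1, 2))
  expect_equal(group_ttest(Xs)$values, 0)
  # constant nonzero column -> capped sentinel, flagged
  Xc <- cbind(rep(3, 5))
  mc <- group_ttest(Xc)
  expect_equal(mc$values, 1e6)
  expect_true(mc$flagged[1])
  expect_error(group_ttest(X[1, , drop = FALSE]), "at least 2")
})

test_that("threshold_map uses inclusive tails and drops flagged voxels", {
  m <- stat_map(c(2.9, 3.0, 3.1, -3.5, 0), "t", n = 10, df = 8)
  expect_equal(threshold_map(m, 3, "positive"), c(2L, 3L))
  expect_equal(threshold_map(m, 3, "negative"), 4L)
  expect_equal(threshold_map(m, 3, "absolute"),
               sort(union(threshold_map(m, 3, "positive"),
                          threshold_map(m, 3, "negative"))))
  expect_length(threshold_map(m, 10), 0)
  mf <- stat_map(c(2.9, 3.0, 3.1, -3.5, 0), "t", n = 10, df = 8,
                 flagged = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(threshold_map(mf, 3, "positive"), 3L)
})

test_that("null cohorts produce calibrated voxelwise t maps", {
  # fraction of |t| above the two-sided p = .003 cutoff should be ~ .003
  tr <- make_truth("null", volume_grid(c(10, 6, 5)))  # 300 voxels
  n <- 20
  crit <- stats::qt(1 - 0.003 / 2, df = n - 2)
  hits <- 0; total <- 0
  for (k in 1:60) {
    ch <- simulate_cohort(n, tr, hcp_covariates(), seed = 1000 + k)
    tmap <- r_to_t(voxelwise_corr(ch$X, ch$y), n = n, q_covariates = 0)
    hits <- hits + sum(abs(tmap$values) >= crit)
    total <- total + length(tmap$values)
  }
  rate <- hits / total
  se <- sqrt(0.003 * 0.997 / total)
  expect_gt(rate, 0.003 - 4 * se)
  expect_lt(rate, 0.003 + 4 * se)
})

test_that("stat maps write to NIfTI with a provenance sidecar", {
  g <- tiny_grid()
  mask <- voxel_mask(g)
  m <- stat_map(rnorm(mask$n_voxels), "t", n = 12, df = 10,
                provenance = "unit test")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_stat_map(m, mask, f)
  back <- load_volume(f)
  expect_equal(vectorize(back$data, mask), m$values, tolerance = 1e-6)
  sidecar <- sub("[.]nii[.]gz$", ".json", f)
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$kind, "t")
  expect_equal(meta$df, 10)
})
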