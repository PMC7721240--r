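# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(shape = c(4, 4, 4)) volume_grid(shape, c(3, 3, 3))

# A small cohort with a localized signal, for pipeline-level tests.
test_cohort <- function(n = 60, shape = c(8, 8, 8), pattern = "localized_strong",
                        seed = 101, cov = hcp_covariates()) {
  truth <- make_truth(pattern, volume_grid(shape), support_radius_vox = 2)
  simulate_cohort(n, truth, cov, seed = seed)
}

# Random stat map on V voxels (kind t so thresholding is meaningful).
random_stat_map <- function(V, sd = 2, n = 20) {
  stat_map(stats::rnorm(V, sd = sd), kind = "t", n = n, df = n - 1)
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- as.integer(append(p, n, after = pos - 1))
    }
  }
  out
}

# Brute-force singular value of the 1 x voxels correlation structure,
# via plain per-voxel cor() calls (independent of col_cor).
brute_singular_value <- function(X, y) {
  r <- apply(X, 2, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(col, y)
  })
  sqrt(sum(r^2))
}

write_toy_cohort_csv <- function(path, ids = c("s1", "s2", "s3"),
                                 stratum = NULL) {
  df <- data.frame(participant_id = ids,
                   behavior = c(0.9, 0.8, 0.7)[seq_along(ids)],
                   age = c(25, 40, 70)[seq_along(ids)],
                   fd = c(0.1, 0.2, 0.3)[seq_along(ids)])
  if (!is.null(stratum)) df$agegroup <- stratum
  utils::write.csv(df, path, row.names = FALSE)
  path
}
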