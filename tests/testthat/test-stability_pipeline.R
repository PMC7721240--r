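small_config <- function(seed = 42, ...) {
  experiment_config(cohort = "hcp_like", pattern = "localized_strong",
                    n = 120, grid = volume_grid(c(8, 8, 8)),
                    schedule = data.frame(size = c(20, 40),
                                          n_subsamples = c(3, 2)),
                    n_perm = 30, n_boot = 30, seed = seed, ...)
}

test_that("report covers the schedule cross product with no silent drops", {
  rep <- run_experiment(small_config())
  # 3 + 2 = 5 PLS records
  expect_equal(nrow(rep$pls_table), 5)
  expect_equal(as.integer(table(rep$pls_table$size)), c(3L, 2L))
  # choose(3,2) + choose(2,2) = 4 pairwise rows per method
  expect_equal(sum(rep$similarity$method == "pls"), 4)
  expect_equal(sum(rep$similarity$method == "univariate"), 4)
  # one univariate and one PLS map per (size, subsample)
  expect_length(rep$maps[["20"]][["univariate"]], 3)
  expect_length(rep$maps[["20"]][["pls"]], 3)
  expect_length(rep$maps[["40"]][["univariate"]], 2)
  # penetration present per size and method
  expect_s3_class(rep$penetration[["20"]][["pls"]], "penetration_map")
  expect_true(all(rep$pls_table$perm_p > 0 & rep$pls_table$perm_p <= 1))
})

test_that("the full pipeline is byte-identical under one seed", {
  cfg <- small_config()
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  report_tables(r1, d1); report_tables(r2, d2)
  for (f in c("similarity_by_size.csv", "pls_by_subsample.csv",
              "overlap_by_size.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  r3 <- run_experiment(small_config(seed = 43))
  expect_false(identical(r1$pls_table, r3$pls_table))
})

test_that("an infeasible schedule aborts with context", {
  cfg <- experiment_config(cohort = "hcp_like", n = 50,
                           grid = volume_grid(c(4, 4, 4)),
                           schedule = data.frame(size = 30, n_subsamples = 2),
                           n_perm = 10, n_boot = 10, seed = 1)
  expect_error(run_experiment(cfg), "infeasible")
})

test_that("cohort-level residualization is available as a config switch", {
  r_sub <- run_experiment(small_config())
  r_coh <- run_experiment(small_config(residualization = "cohort"))
  expect_false(identical(r_sub$pls_table$r_brainscore_behavior,
                         r_coh$pls_table$r_brainscore_behavior))
  expect_equal(nrow(r_coh$pls_table), 5)
})

test_that("null-truth cohorts show near-zero thresholded-map stability", {
  cfg <- experiment_config(cohort = "hcp_like", pattern = "null", n = 120,
                           grid = volume_grid(c(8, 8, 8)),
                           schedule = data.frame(size = c(20, 40),
                                                 n_subsamples = c(3, 2)),
                           n_perm = 20, n_boot = 20, seed = 7)
  rep <- run_experiment(cfg)
  expect_lt(max(rep$summary$mean_jaccard), 0.1)
})

test_that("report_tables writes the documented CSVs and respects the plot flag", {
  rep <- run_experiment(small_config())
  d <- withr::local_tempdir()
  report_tables(rep, d, plots = FALSE)
  expect_setequal(list.files(d), c("similarity_by_size.csv",
                                   "pls_by_subsample.csv",
                                   "overlap_by_size.csv"))
  sim <- utils::read.csv(file.path(d, "similarity_by_size.csv"))
  expect_true(all(c("size", "method", "mean_rho", "mean_jaccard") %in%
                    names(sim)))
  pls <- utils::read.csv(file.path(d, "pls_by_subsample.csv"))
  expect_equal(nrow(pls), nrow(rep$pls_table))
})

test_that("run_experiment writes maps, penetration volumes and subsample JSON", {
  d <- withr::local_tempdir()
  rep <- run_experiment(small_config(out_dir = d))
  files <- list.files(d)
  expect_true("penetration_pls_size20.nii.gz" %in% files)
  expect_true("subsamples_size20.json" %in% files)
  pm <- load_volume(file.path(d, "penetration_pls_size20.nii.gz"))
  expect_equal(max(pm$data), max(rep$penetration[["20"]][["pls"]]$reported))
})

test_that("compare_methods reproduces a hand-computed paired t", {
  rep <- run_experiment(small_config())
  cm <- compare_methods(rep)
  expect_equal(cm$df, 1)  # two sizes
  # hand computation on a toy 3-size table
  toy <- structure(list(summary = data.frame(
    size = rep(c(20, 40, 80), 2),
    method = rep(c("pls", "univariate"), each = 3),
    n_pairs = 1, mean_rho = 0.5, sd_rho = 0,
    mean_jaccard = c(0.3, 0.5, 0.6, 0.1, 0.2, 0.4),
    sd_jaccard = 0, mean_overlap = 0)), class = "stability_report")
  cm_toy <- compare_methods(toy)
  d <- c(0.2, 0.3, 0.2)
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(cm_toy$t, t_hand, tolerance = 1e-12)
  expect_equal(cm_toy$df, 2)
  # identical methods give t = 0
  same <- toy
  same$summary$mean_jaccard <- rep(c(0.3, 0.5, 0.6), 2)
  cm_same <- compare_methods(same)
  expect_equal(cm_same$t, 0)
  single <- structure(list(summary = toy$summary[toy$summary$size == 20, ]),
                      class = "stability_report")
  expect_error(compare_methods(single), "2 sizes")
})
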