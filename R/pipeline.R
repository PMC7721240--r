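# Orchestration: cohort -> subsample schedule -> per-subsample univariate
# and PLS maps -> similarity / penetration / summary tables.

#' Build an experiment configuration
#'
#' @param cohort Cohort source: a `cohort` object, a preset name
#'   (`"dallas_like"`, `"hcp_like"`), or a directory path written by
#'   [write_cohort()].
#' @param pattern Truth pattern for simulated presets
#'   (`"localized_strong"`, `"diffuse_weak"`, `"null"`).
#' @param n Optional override of the preset sample size.
#' @param grid [volume_grid] for simulated presets.
#' @param schedule `"dallas"`, `"hcp"`, or a [subsample_schedule] /
#'   two-column data frame (`size`, `n_subsamples`).
#' @param threshold Map threshold for Jaccard/penetration (default 3).
#' @param tail Thresholding tail (default `"positive"`).
#' @param n_perm,n_boot PLS resampling settings (defaults 1000; reduce for
#'   desk-scale runs).
#' @param seed Master seed; the whole experiment is a pure function of the
#'   configuration including this seed.
#' @param residualization `"subsample"` (default): age/FD are regressed out
#'   of brain and behavior within each analysis subsample, matching a
#'   per-analysis nuisance correction; `"cohort"`: residualize once on the
#'   full cohort before subsampling.
#' @param stratified Use stratified draws? Default `NULL` = stratify when
#'   the cohort has strata and every scheduled size is divisible by the
#'   stratum count.
#' @param out_dir Optional output directory; when set, maps, penetration
#'   volumes, subsample JSON and tables are written there.
#' @param verbose Log one line per (size, subsample).
#' @return Object of class `experiment_config` (a list).
#' @export
experiment_config <- function(cohort = "hcp_like",
                              pattern = "localized_strong",
                              n = NULL, grid = default_grid(),
                              schedule = "hcp",
                              threshold = 3, tail = "positive",
                              n_perm = 1000, n_boot = 1000,
                              seed = 1L,
                              residualization = c("subsample", "cohort"),
                              stratified = NULL,
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(is.finite(threshold))
  structure(list(cohort = cohort, pattern = pattern, n = n, grid = grid,
                 schedule = schedule, threshold = threshold, tail = tail,
                 n_perm = n_perm, n_boot = n_boot, seed = as.integer(seed),
                 residualization = match.arg(residualization),
                 stratified = stratified,
                 out_dir = out_dir, verbose = verbose),
            class = "experiment_config")
}

resolve_schedule <- function(schedule) {
  if (is.character(schedule)) return(default_schedule(schedule))
  if (is.list(schedule) && all(c("size", "n_subsamples") %in% names(schedule))) {
    return(subsample_schedule(schedule$size, schedule$n_subsamples))
  }
  stop("schedule must be a design name or a table with size and n_subsamples")
}

resolve_cohort <- function(config) {
  ch <- config$cohort
  if (inherits(ch, "cohort")) return(ch)
  if (is.character(ch) && length(ch) == 1) {
    if (ch %in% c("dallas_like", "hcp_like")) {
      truth <- make_truth(config$pattern, config$grid)
      return(simulate_preset_cohort(ch, truth, seed = derive_seed(config$seed, "cohort"),
                                    n = config$n))
    }
    if (dir.exists(ch)) return(read_cohort(ch))
    stop("unknown cohort source: ", ch)
  }
  stop("cohort must be a cohort object, preset name, or directory")
}

#' Run the full stability experiment
#'
#' For each (size, subsample) in the schedule: residualize age and FD from
#' both brain and behavior, compute the univariate correlation -> t map and
#' the behavioral PLS result, then within each size compute the pairwise
#' Spearman/Jaccard table and the penetration map for both methods.
#'
#' @param config An [experiment_config()].
#' @return Object of class `stability_report`: list with
#'   \describe{
#'     \item{pls_table}{one row per (size, subsample): singular value,
#'       brain-score-behavior correlation, permutation p.}
#'     \item{similarity}{pairwise similarity rows for both methods.}
#'     \item{summary}{per-(size, method) means from [overlap_summary()].}
#'     \item{penetration}{nested list `[[size]][[method]]` of
#'       [penetration()] results.}
#'     \item{maps}{nested list `[[size]][[method]]` of per-subsample
#'       [stat_map]s (t maps for `univariate`, BSR maps for `pls`).}
#'     \item{subsamples}{list of `subsample_set`s, one per size.}
#'     \item{cohort_info, settings}{provenance.}
#'   }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config)
  sched <- resolve_schedule(config$schedule)
  n_total <- nrow(cohort$X)
  if (any(sched$size * sched$n_subsamples > n_total)) {
    bad <- sched$size[sched$size * sched$n_subsamples > n_total]
    stop("schedule infeasible for cohort of ", n_total, " at size(s) ",
         paste(bad, collapse = ", "))
  }
  strata <- NULL
  if (!is.null(cohort$strata)) {
    k <- nlevels(as.factor(cohort$strata))
    use <- config$stratified %||% all(sched$size %% k == 0)
    if (isTRUE(use)) strata <- cohort$strata
  }
  q <- ncol(cohort$C)
  X <- cohort$X; y <- cohort$y; C <- cohort$C
  if (config$residualization == "cohort") {
    X <- residualize(X, C)
    y <- residualize(y, C)
  }

  pls_rows <- list(); sim_rows <- list()
  penet <- list(); maps <- list(); subsamples <- list()
  for (e in seq_len(nrow(sched))) {
    size <- sched$size[e]; count <- sched$n_subsamples[e]
    ss <- draw_subsamples(n_total, size, count, strata = strata,
                          rng_seed = derive_seed(config$seed, "draw"))
    subsamples[[as.character(size)]] <- ss
    t_maps <- vector("list", count); bsr_maps <- vector("list", count)
    for (j in seq_len(count)) {
      idx <- ss$index_sets[[j]]
      Xs <- X[idx, , drop = FALSE]; ys <- y[idx]
      if (config$residualization == "subsample") {
        Cs <- C[idx, , drop = FALSE]
        Xs <- residualize(Xs, Cs)
        ys <- residualize(ys, Cs)
      }
      tag <- sprintf("size=%d subsample=%d", size, j)
      t0 <- proc.time()[["elapsed"]]
      rmap <- voxelwise_corr(Xs, ys, provenance = paste("univariate", tag))
      t_maps[[j]] <- r_to_t(rmap, n = size, q_covariates = q)
      pls <- run_behavioral_pls(Xs, ys, n_perm = config$n_perm,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed, "pls", size, j))
      bsr_maps[[j]] <- stat_map(pls$bsr, kind = "bsr", n = size,
                                flagged = pls$bsr_flagged | rmap$flagged,
                                provenance = paste("pls", tag))
      pls_rows[[length(pls_rows) + 1]] <- data.frame(
        size = size, subsample = j,
        singular_value = pls$singular_value,
        r_brainscore_behavior = pls$r_brainscore_behavior,
        perm_p = pls$perm_p)
      if (isTRUE(config$verbose)) {
        message(sprintf("[brainstab] %s done in %.1fs (seed %d)", tag,
                        proc.time()[["elapsed"]] - t0,
                        derive_seed(config$seed, "pls", size, j)))
      }
    }
    for (method in c("univariate", "pls")) {
      mm <- if (method == "univariate") t_maps else bsr_maps
      maps[[as.character(size)]][[method]] <- mm
      if (count >= 2) {
        sim_rows[[length(sim_rows) + 1]] <-
          pairwise_similarity(mm, threshold = config$threshold,
                              tail = config$tail, size = size, method = method)
        penet[[as.character(size)]][[method]] <-
          penetration(mm, threshold = config$threshold, tail = config$tail)
      }
    }
  }
  sim_all <- if (length(sim_rows)) do.call(rbind, sim_rows) else NULL
  report <- structure(list(
    pls_table = do.call(rbind, pls_rows),
    similarity = sim_all,
    summary = if (is.null(sim_all)) NULL else overlap_summary(sim_all),
    penetration = penet,
    maps = maps,
    subsamples = subsamples,
    cohort_info = list(n = n_total, n_voxels = cohort$mask$n_voxels,
                       pattern = if (is.null(cohort$truth)) NA_character_
                                 else cohort$truth$pattern_kind,
                       stratified = !is.null(strata)),
    mask = cohort$mask,
    truth = cohort$truth,
    settings = config[c("threshold", "tail", "n_perm", "n_boot", "seed",
                        "residualization")]),
    class = "stability_report")
  if (!is.null(config$out_dir)) {
    report_tables(report, config$out_dir)
    write_report_volumes(report, config$out_dir)
    for (s in names(subsamples)) {
      write_subsamples(subsamples[[s]],
                       file.path(config$out_dir, sprintf("subsamples_size%s.json", s)))
    }
  }
  report
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> cohort n=%d, %d sizes, threshold %g (%s tail)\n",
              x$cohort_info$n, length(x$maps), x$settings$threshold,
              x$settings$tail))
  print(x$summary)
  invisible(x)
}

#' Write report tables (and optional figures)
#'
#' Writes `similarity_by_size.csv` (per-size mean/SD rho and Jaccard per
#' method), `pls_by_subsample.csv` (per-subsample PLS record) and
#' `overlap_by_size.csv` (mean overlapping-voxel counts). With
#' `plots = TRUE` (requires ggplot2), also writes stability and PLS curves
#' as PNG files.
#'
#' @param report A `stability_report`.
#' @param dir Output directory.
#' @param plots Render figures (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
report_tables <- function(report, dir, plots = FALSE) {
  stopifnot(inherits(report, "stability_report"))
  if (is.null(report$summary) || is.null(report$pls_table)) {
    stop("incomplete report")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "similarity_by_size.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pls_table, file.path(dir, "pls_by_subsample.csv"),
                   row.names = FALSE)
  ov <- report$summary[, c("size", "method", "n_pairs", "mean_overlap")]
  utils::write.csv(ov, file.path(dir, "overlap_by_size.csv"), row.names = FALSE)
  if (isTRUE(plots)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      stop("plots = TRUE requires ggplot2")
    }
    g1 <- ggplot2::ggplot(report$summary,
                          ggplot2::aes(x = size, colour = method)) +
      ggplot2::geom_line(ggplot2::aes(y = mean_rho, linetype = "rho")) +
      ggplot2::geom_line(ggplot2::aes(y = mean_jaccard, linetype = "jaccard")) +
      ggplot2::labs(y = "mean similarity", linetype = "metric")
    ggplot2::ggsave(file.path(dir, "similarity_by_size.png"), g1,
                    width = 6, height = 4, dpi = 120)
    g2 <- ggplot2::ggplot(report$pls_table, ggplot2::aes(x = size)) +
      ggplot2::geom_point(ggplot2::aes(y = r_brainscore_behavior)) +
      ggplot2::geom_point(ggplot2::aes(y = perm_p), colour = "red") +
      ggplot2::labs(y = "r (black) / perm p (red)")
    ggplot2::ggsave(file.path(dir, "pls_by_size.png"), g2,
                    width = 6, height = 4, dpi = 120)
  }
  invisible(dir)
}

# Write penetration maps as integer NIfTI volumes.
write_report_volumes <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(report$penetration)) {
    for (method in names(report$penetration[[s]])) {
      pm <- report$penetration[[s]][[method]]
      vol <- devectorize(pm$reported, report$mask, fill = 0)
      save_volume(vol, report$mask$grid,
                  file.path(dir, sprintf("penetration_%s_size%s.nii.gz", method, s)),
                  datatype = "int16")
    }
  }
  invisible(dir)
}

#' Paired comparison of Jaccard stability between methods
#'
#' Pairs the per-size mean Jaccard of the PLS and univariate arms and tests
#' their difference with a paired t test over sizes (df = number of sizes
#' minus 1).
#'
#' @param report A `stability_report` covering both methods at >= 2 sizes.
#' @return List with `table` (per-size mean Jaccard per method and the
#'   paired difference), `t`, `df`, `p_value`, `mean_difference`.
#' @export
compare_methods <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  s <- report$summary
  wide <- merge(s[s$method == "pls", c("size", "mean_jaccard")],
                s[s$method == "univariate", c("size", "mean_jaccard")],
                by = "size", suffixes = c("_pls", "_univariate"))
  if (nrow(wide) < 2) stop("need both methods at >= 2 sizes for a paired comparison")
  wide$difference <- wide$mean_jaccard_pls - wide$mean_jaccard_univariate
  if (stats::sd(wide$difference) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = nrow(wide) - 1),
               p.value = 1)
  } else {
    tt <- stats::t.test(wide$mean_jaccard_pls, wide$mean_jaccard_univariate,
                        paired = TRUE)
  }
  list(table = wide,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(wide$difference))
}
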