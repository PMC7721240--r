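# Synthetic cohort generation: covariate structure with a target Pearson
# correlation matrix among (age, FD, behavior), plus per-voxel contrast
# values carrying an embedded brain-behavior correlation pattern.

#' Covariate correlation structure for cohort simulation
#'
#' Describes the joint distribution of age (years), mean frame displacement
#' (FD, mm) and the behavioral score (proportion correct): a 3x3 target
#' Pearson correlation matrix plus marginal means/SDs and a clipping range
#' for behavior. The variable order is fixed as (age, FD, behavior).
#'
#' Age can follow either a plain normal marginal (`age_marginal = "normal"`)
#' or an equal-weight mixture of uniforms over four age brackets
#' (`"grouped_uniform"`), the latter producing a cohort balanced across age
#' groups, as cross-sectional aging studies that stratify recruitment by
#' decade are. With the grouped marginal, age is a monotone transform of its
#' Gaussian latent; the slight Pearson attenuation this induces is
#' pre-compensated numerically so the target correlations are achieved.
#'
#' @param correlation 3x3 correlation matrix (age, FD, behavior); symmetric,
#'   unit diagonal, positive semi-definite.
#' @param age_mean,age_sd Age marginal (years); used only when
#'   `age_marginal = "normal"`.
#' @param fd_mean,fd_sd FD marginal (mm).
#' @param behavior_mean,behavior_sd Behavior marginal (proportion correct).
#' @param behavior_clip Length-2 clipping range for behavior.
#' @param age_marginal `"normal"` or `"grouped_uniform"`.
#' @param age_brackets For `"grouped_uniform"`: numeric vector of 5 break
#'   points defining 4 age brackets.
#' @return Object of class `covariate_structure`.
#' @export
covariate_structure <- function(correlation,
                                age_mean = 50, age_sd = 15,
                                fd_mean = 0.2, fd_sd = 0.08,
                                behavior_mean = 0.8, behavior_sd = 0.1,
                                behavior_clip = c(0, 1),
                                age_marginal = c("normal", "grouped_uniform"),
                                age_brackets = c(20, 35.5, 55.5, 69.5, 94)) {
  age_marginal <- match.arg(age_marginal)
  correlation <- unname(as.matrix(correlation))
  if (!all(dim(correlation) == c(3, 3))) stop("correlation must be 3x3")
  if (max(abs(correlation - t(correlation))) > 1e-12) stop("correlation must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12) stop("correlation must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("correlation matrix is not positive semi-definite")
  stopifnot(behavior_clip[1] < behavior_clip[2])
  structure(list(correlation = correlation,
                 age_mean = age_mean, age_sd = age_sd,
                 fd_mean = fd_mean, fd_sd = fd_sd,
                 behavior_mean = behavior_mean, behavior_sd = behavior_sd,
                 behavior_clip = behavior_clip,
                 age_marginal = age_marginal,
                 age_brackets = age_brackets),
            class = "covariate_structure")
}

#' Named covariate presets
#'
#' `dallas_covariates()`: an aging working-memory cohort — age-FD r = 0.46,
#' age-behavior r = -0.48, FD-behavior r = -0.29, ages spanning 20-94 years
#' balanced over four age brackets (20-35, 36-55, 56-69, 70-94).
#' `hcp_covariates()`: a young-adult cohort — age-FD r = 0.12, age-behavior
#' r = -0.09, FD-behavior r = -0.19, ages 22-36 (mean 28.72, SD 3.74).
#'
#' @return A [covariate_structure].
#' @export
dallas_covariates <- function() {
  R <- matrix(c(1, 0.46, -0.48,
                0.46, 1, -0.29,
                -0.48, -0.29, 1), 3, 3)
  covariate_structure(R,
                      age_mean = 53.03, age_sd = 19.13,
                      fd_mean = 0.30, fd_sd = 0.12,
                      behavior_mean = 0.75, behavior_sd = 0.10,
                      behavior_clip = c(0, 1),
                      age_marginal = "grouped_uniform",
                      age_brackets = c(20, 35.5, 55.5, 69.5, 94))
}

#' @rdname dallas_covariates
#' @export
hcp_covariates <- function() {
  R <- matrix(c(1, 0.12, -0.09,
                0.12, 1, -0.19,
                -0.09, -0.19, 1), 3, 3)
  covariate_structure(R,
                      age_mean = 28.72, age_sd = 3.74,
                      fd_mean = 0.15, fd_sd = 0.05,
                      behavior_mean = 0.80, behavior_sd = 0.10,
                      behavior_clip = c(0, 1),
                      age_marginal = "normal")
}

# Quantile function of the equal-weight mixture of uniforms over the four
# age brackets, evaluated at u in (0, 1).
grouped_uniform_quantile <- function(u, brackets) {
  k <- length(brackets) - 1
  s <- pmin(k, floor(u * k) + 1)
  lo <- brackets[s]
  w <- brackets[s + 1] - brackets[s]
  lo + (u * k - (s - 1)) * w
}

# Pearson attenuation factor c = corr(g(Z), Z) for the monotone map g from a
# standard normal to the grouped-uniform age marginal, computed by a fixed
# deterministic quadrature over the uniform scale.
grouped_uniform_attenuation <- function(brackets, m = 200000L) {
  u <- (seq_len(m) - 0.5) / m
  g <- grouped_uniform_quantile(u, brackets)
  q <- stats::qnorm(u)
  stats::cor(g, q)
}

#' Simulate covariates (age, FD, behavior)
#'
#' Draws `n` joint observations whose Pearson correlation structure matches
#' the target matrix in `cov`: a trivariate Gaussian latent built by Cholesky
#' factorization, scaled to the marginals. With the grouped-uniform age
#' marginal the age latent's rank is mapped through the mixture quantile
#' function (balanced age groups by construction) and the latent correlation
#' is inflated by the numerically computed attenuation factor so the target
#' Pearson correlations still hold.
#'
#' @param n Number of participants.
#' @param cov A [covariate_structure].
#' @param seed Integer seed.
#' @return List with `age`, `fd`, `behavior` (clipped), `behavior_latent`
#'   (standardized pre-clipping latent), `strata` (factor over age brackets
#'   for grouped marginals, else `NULL`).
#' @export
simulate_covariates <- function(n, cov, seed) {
  stopifnot(inherits(cov, "covariate_structure"), n >= 2)
  R <- cov$correlation
  if (cov$age_marginal == "grouped_uniform") {
    cc <- grouped_uniform_attenuation(cov$age_brackets)
    R[1, 2] <- R[2, 1] <- R[1, 2] / cc
    R[1, 3] <- R[3, 1] <- R[1, 3] / cc
    if (any(abs(R) > 1)) stop("compensated latent correlation exceeds 1; target infeasible")
  }
  L <- tryCatch(chol(R), error = function(e) stop("correlation matrix is not positive definite"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  if (cov$age_marginal == "grouped_uniform") {
    u <- (rank(Z[, 1], ties.method = "first") - 0.5) / n
    age <- grouped_uniform_quantile(u, cov$age_brackets)
    strata <- cut(age, breaks = cov$age_brackets, include.lowest = TRUE,
                  labels = paste0(ceiling(cov$age_brackets[-length(cov$age_brackets)]),
                                  "-", floor(cov$age_brackets[-1])))
  } else {
    age <- cov$age_mean + cov$age_sd * Z[, 1]
    strata <- NULL
  }
  fd <- cov$fd_mean + cov$fd_sd * Z[, 2]
  behavior_latent <- Z[, 3]
  behavior <- pmin(cov$behavior_clip[2],
                   pmax(cov$behavior_clip[1],
                        cov$behavior_mean + cov$behavior_sd * behavior_latent))
  list(age = age, fd = fd, behavior = behavior,
       behavior_latent = behavior_latent, strata = strata)
}

#' Simulate a full synthetic cohort
#'
#' Generates covariates via [simulate_covariates()] and a participants x
#' voxels matrix of contrast values in which voxel `v` carries population
#' correlation `rho_v` with the (pre-clipping) behavioral latent:
#' `X[i, v] = rho_v * z_i + sqrt(1 - rho_v^2) * eps[i, v]` with `z` the
#' standardized behavior latent and independent standard-normal noise. The
#' correlation is embedded against the latent, not the clipped score; the
#' clipping distortion is small at the default marginals and is measured in
#' the test suite rather than assumed away.
#'
#' @param n Number of participants (>= 4).
#' @param truth A `truth_spec` from [make_truth()].
#' @param cov A [covariate_structure].
#' @param seed Integer seed; the cohort is a pure function of
#'   `(n, truth, cov, seed)`.
#' @param age_loading Optional per-voxel numeric vector (length = number of
#'   voxels): adds `age_loading[v] * z_age` to voxel `v`, giving covariate
#'   signal in the brain so that residualization has something to remove.
#'   Default `NULL` (off): truth is a pure brain-behavior correlation.
#' @return Object of class `cohort`: list with `X` (n x voxels matrix), `y`
#'   (behavior), `C` (n x 2 matrix, columns `age`, `fd`), `mask`
#'   ([voxel_mask], full grid), `strata`, `truth`, `participant_id`, `seed`.
#' @export
simulate_cohort <- function(n, truth, cov, seed, age_loading = NULL) {
  stopifnot(inherits(truth, "truth_spec"), inherits(cov, "covariate_structure"))
  if (n < 4) stop("need at least 4 participants")
  covs <- simulate_covariates(n, cov, derive_seed(seed, "covariates"))
  mask <- voxel_mask(truth$grid)
  rho <- vectorize(truth$rho_map, mask)
  V <- mask$n_voxels
  z <- covs$behavior_latent
  set.seed(derive_seed(seed, "voxel-noise"))
  eps <- matrix(stats::rnorm(n * V), n, V)
  if (is.null(age_loading)) {
    X <- outer(z, rho) + eps * rep(sqrt(1 - rho^2), each = n)
  } else {
    stopifnot(length(age_loading) == V)
    if (any(rho^2 + age_loading^2 >= 1)) stop("rho^2 + age_loading^2 must stay below 1")
    zage <- as.numeric(scale(covs$age))
    X <- outer(z, rho) + outer(zage, age_loading) +
      eps * rep(sqrt(1 - rho^2 - age_loading^2), each = n)
  }
  C <- cbind(age = covs$age, fd = covs$fd)
  structure(list(X = X, y = covs$behavior, C = C, mask = mask,
                 strata = covs$strata, truth = truth,
                 participant_id = sprintf("sub-%04d", seq_len(n)),
                 seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants x %d voxels (%s truth)%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$truth)) "unknown" else x$truth$pattern_kind,
              if (is.null(x$strata)) "" else sprintf(", %d strata", nlevels(x$strata))))
  invisible(x)
}

#' Named cohort presets
#'
#' `"dallas_like"`: n = 171, Dallas covariate structure, age-bracket strata.
#' `"hcp_like"`: n = 865, HCP covariate structure, no strata.
#'
#' @param preset `"dallas_like"` or `"hcp_like"`.
#' @param truth A `truth_spec`; default a localized strong pattern on the
#'   default grid.
#' @param seed Integer seed.
#' @param n Override the preset's sample size (e.g. for desk-scale runs).
#' @return A `cohort`.
#' @export
simulate_preset_cohort <- function(preset = c("dallas_like", "hcp_like"),
                                   truth = make_truth("localized_strong"),
                                   seed = 1L, n = NULL) {
  preset <- match.arg(preset)
  if (preset == "dallas_like") {
    simulate_cohort(n %||% 171L, truth, dallas_covariates(), seed)
  } else {
    simulate_cohort(n %||% 865L, truth, hcp_covariates(), seed)
  }
}

#' Write a cohort to disk
#'
#' Layout: `<dir>/sub-XXXX_contrast.nii.gz` (one float volume per
#' participant), `<dir>/mask.nii.gz`, `<dir>/participants.csv`,
#' `<dir>/truth_rho.nii.gz` (when truth is present) and `<dir>/config.yaml`
#' echoing the generation parameters. Re-ingestable with [read_cohort()].
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$mask$grid
  n <- nrow(cohort$X)
  for (i in seq_len(n)) {
    vol <- devectorize(cohort$X[i, ], cohort$mask, fill = NaN)
    save_volume(vol, grid, file.path(dir, paste0(cohort$participant_id[i], "_contrast.nii.gz")))
  }
  save_volume(array(as.numeric(cohort$mask$in_mask), dim = grid$shape),
              grid, file.path(dir, "mask.nii.gz"))
  tab <- data.frame(participant_id = cohort$participant_id,
                    behavior = cohort$y,
                    age = cohort$C[, "age"], fd = cohort$C[, "fd"])
  if (!is.null(cohort$strata)) tab$stratum <- as.character(cohort$strata)
  utils::write.csv(tab, file.path(dir, "participants.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    save_volume(cohort$truth$rho_map, grid, file.path(dir, "truth_rho.nii.gz"))
  }
  cfg <- list(n = n, seed = cohort$seed,
              grid = list(shape = grid$shape, voxel_size_mm = grid$voxel_size_mm),
              pattern_kind = if (is.null(cohort$truth)) NA else cohort$truth$pattern_kind)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Reads the [write_cohort()] layout, or any directory holding one NIfTI
#' contrast volume per participant plus a mask and a participants table.
#' Voxels that are NaN in any participant's volume (or outside the mask) are
#' removed from the analysis mask at assembly, mirroring the removal of
#' voxels estimated as NA due to low signal in first-level processing.
#'
#' @param dir Directory written by [write_cohort()], or containing the same
#'   layout.
#' @param table_args Optional list of arguments passed to
#'   [read_cohort_table()] (column names).
#' @return A `cohort` (with `truth` when `truth_rho.nii.gz` is present).
#' @export
read_cohort <- function(dir, table_args = list()) {
  tab <- do.call(read_cohort_table,
                 c(list(file.path(dir, "participants.csv")), table_args))
  mask <- load_mask(file.path(dir, "mask.nii.gz"))
  grid <- mask$grid
  n <- nrow(tab)
  vols <- matrix(NA_real_, n, mask$n_voxels)
  for (i in seq_len(n)) {
    path <- file.path(dir, paste0(tab$participant_id[i], "_contrast.nii.gz"))
    if (!file.exists(path)) path <- sub("[.]gz$", "", path)
    v <- load_volume(path, expected_grid = grid)
    vols[i, ] <- vectorize(v$data, mask)
  }
  # drop voxels NaN/NA in any participant from the analysis mask
  bad <- colSums(!is.finite(vols)) > 0
  if (any(bad)) {
    keep_arr <- mask$in_mask
    keep_arr[mask$in_mask][bad] <- FALSE
    mask <- voxel_mask(grid, keep_arr)
    vols <- vols[, !bad, drop = FALSE]
  }
  truth <- NULL
  truth_path <- file.path(dir, "truth_rho.nii.gz")
  if (file.exists(truth_path)) {
    tv <- load_volume(truth_path, expected_grid = grid)
    truth <- make_truth("custom", grid, rho_map = tv$data)
  }
  covariate_cols <- attr(tab, "covariate_cols") %||% c("age", "fd")
  C <- as.matrix(tab[, covariate_cols, drop = FALSE])
  colnames(C) <- covariate_cols
  structure(list(X = vols, y = tab$behavior, C = C, mask = mask,
                 strata = tab$stratum, truth = truth,
                 participant_id = tab$participant_id, seed = NA_integer_),
            class = "cohort")
}
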