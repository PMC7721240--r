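# Univariate ("SPM-style") arm: nuisance residualization, voxelwise
# correlation and t maps, one-sample task-effect t map, thresholding.

# Sentinel used where a t statistic is formally infinite (|r| = 1, or zero
# within-voxel variance with nonzero mean).
T_CAP <- 1e6

#' Per-voxel statistic map
#'
#' A `stat_map` holds one statistic value per masked voxel together with its
#' kind and provenance. All maps in the pipeline share the fixed masked-voxel
#' order of [vectorize()].
#'
#' @param values Numeric vector over masked voxels.
#' @param kind One of `"r"`, `"t"`, `"salience"`, `"bsr"`, `"count"`.
#' @param n Participants used.
#' @param df Degrees of freedom (for `"t"`), else `NA`.
#' @param flagged Logical vector marking degenerate voxels (e.g. zero
#'   variance); flagged voxels are excluded from thresholded sets.
#' @param provenance Free-text provenance (method, subsample id, threshold).
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(values, kind = c("r", "t", "salience", "bsr", "count"),
                     n = NA_integer_, df = NA_real_, flagged = NULL,
                     provenance = "") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "r" && any(abs(values) > 1 + 1e-12)) stop("r values must lie in [-1, 1]")
  if (kind == "t" && !is.na(df) && df < 1) stop("t maps need df >= 1")
  if (is.null(flagged)) flagged <- rep(FALSE, length(values))
  stopifnot(length(flagged) == length(values))
  structure(list(values = values, kind = kind, n = as.integer(n), df = df,
                 flagged = flagged, provenance = provenance),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> kind=%s, %d voxels, n=%s%s%s\n", x$kind,
              length(x$values), x$n,
              if (is.na(x$df)) "" else sprintf(", df=%g", x$df),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Residualize values against nuisance covariates
#'
#' Ordinary least-squares residuals of each column of `values` against an
#' intercept plus the covariate columns. Residuals are orthogonal to every
#' covariate, so a subsequent correlation between residualized brain values
#' and residualized behavior is the partial correlation given the
#' covariates.
#'
#' @param values Numeric vector or matrix (rows = participants).
#' @param covariates Participants x q numeric matrix.
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, covariates) {
  vec <- is.null(dim(values))
  V <- if (vec) cbind(values) else as.matrix(values)
  Cm <- as.matrix(covariates)
  if (nrow(V) != nrow(Cm)) stop("values and covariates disagree on row count")
  q <- ncol(Cm)
  if (nrow(V) < q + 2) stop("need at least q + 2 participants to residualize")
  D <- cbind(1, Cm)
  qr_D <- qr(D)
  if (qr_D$rank < ncol(D)) stop("covariate design is rank-deficient after adding an intercept")
  res <- qr.resid(qr_D, V)
  if (vec) as.numeric(res) else res
}

#' Voxelwise Pearson correlation map
#'
#' Correlates each voxel's values across participants with the behavioral
#' score. Zero-variance voxels get a correlation of 0 and are flagged (so downstream
#' similarity metrics never propagate NaN and thresholded sets never include
#' them).
#'
#' @param X Participants x voxels matrix.
#' @param y Behavior vector.
#' @param provenance Provenance string stored in the result.
#' @return A [stat_map] of kind `"r"`.
#' @export
voxelwise_corr <- function(X, y, provenance = "voxelwise_corr") {
  X <- as.matrix(X)
  if (nrow(X) < 4) stop("need at least 4 participants")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  cc <- col_cor(X, y)
  if (cc$y_constant) stop("behavior is constant; correlation undefined")
  stat_map(cc$r, kind = "r", n = nrow(X), flagged = cc$zero_var,
           provenance = provenance)
}

#' Convert a correlation map to a t map
#'
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - q_covariates`, matching
#' a second-level regression on behavior plus `q` nuisance covariates and an
#' intercept. `|r| = 1` maps to the capped sentinel `1e6` (sign kept).
#'
#' @param map A [stat_map] of kind `"r"`.
#' @param n Participants; defaults to `map$n`.
#' @param q_covariates Number of nuisance covariates regressed out upstream
#'   (default 2: age and FD).
#' @return A [stat_map] of kind `"t"` with `df = n - 2 - q_covariates`.
#' @export
r_to_t <- function(map, n = map$n, q_covariates = 2) {
  stopifnot(inherits(map, "stat_map"), map$kind == "r")
  df <- n - 2 - q_covariates
  if (is.na(df) || df < 1) stop("df = n - 2 - q must be >= 1")
  r <- map$values
  t_vals <- ifelse(abs(r) >= 1, sign(r) * T_CAP, r * sqrt(df / (1 - r^2)))
  t_vals <- pmin(T_CAP, pmax(-T_CAP, t_vals))
  stat_map(t_vals, kind = "t", n = n, df = df, flagged = map$flagged,
           provenance = paste0(map$provenance, " -> t(df=", df, ")"))
}

#' One-sample t map (task effect surrogate)
#'
#' Tests each voxel's mean contrast value against zero across participants
#' (df = n - 1): the second-level surrogate for "task versus control"
#' activation on contrast images. Zero-variance voxels get the capped
#' sentinel (nonzero mean) or 0 (zero mean) and are flagged.
#'
#' @param X Participants x voxels matrix.
#' @return A [stat_map] of kind `"t"`.
#' @export
group_ttest <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 participants")
  m <- colMeans(X)
  s <- sqrt(colSums((X - rep(m, each = n))^2) / (n - 1))
  se <- s / sqrt(n)
  zero_var <- se <= 0
  t_vals <- ifelse(zero_var, ifelse(m == 0, 0, sign(m) * T_CAP), m / ifelse(se > 0, se, 1))
  t_vals <- pmin(T_CAP, pmax(-T_CAP, t_vals))
  stat_map(t_vals, kind = "t", n = n, df = n - 1, flagged = zero_var,
           provenance = "group_ttest")
}

#' Threshold a statistic map
#'
#' Inclusive comparison: `positive` keeps voxels with `value >= threshold`,
#' `negative` keeps `value <= -threshold`, `absolute` their union. Flagged
#' (degenerate) voxels never survive.
#'
#' @param map A [stat_map].
#' @param threshold Finite threshold (default 3, the conventional uncorrected
#'   cutoff for both t and bootstrap-ratio maps, approximate voxel-level
#'   p = .003).
#' @param tail `"positive"`, `"negative"` or `"absolute"`.
#' @return Sorted integer vector of surviving masked-voxel indices.
#' @export
threshold_map <- function(map, threshold = 3,
                          tail = c("positive", "negative", "absolute")) {
  stopifnot(inherits(map, "stat_map"), is.finite(threshold))
  tail <- match.arg(tail)
  v <- map$values
  keep <- switch(tail,
                 positive = v >= threshold,
                 negative = v <= -threshold,
                 absolute = v >= threshold | v <= -threshold)
  keep[map$flagged] <- FALSE
  which(keep)
}

#' Write a stat map as a NIfTI volume with a JSON provenance sidecar
#'
#' @param map A [stat_map].
#' @param mask The [voxel_mask] the map lives on.
#' @param path Output `.nii`/`.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, mask, path) {
  stopifnot(inherits(map, "stat_map"), inherits(mask, "voxel_mask"))
  vol <- devectorize(map$values, mask, fill = NaN)
  save_volume(vol, mask$grid, path)
  sidecar <- sub("([.]nii)([.]gz)?$", ".json", path)
  jsonlite::write_json(list(kind = map$kind, n = map$n, df = map$df,
                            n_flagged = sum(map$flagged),
                            provenance = map$provenance),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
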