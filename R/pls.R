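# Behavioral partial least squares for a single behavioral measure and one
# image per participant. With one behavioral variable the brain-behavior
# correlation "matrix" is 1 x voxels, and its SVD has a closed form: the
# singular value is the Euclidean norm of the voxelwise correlation vector
# and the (single) salience map is that vector normalized to unit length.
# Inference is by permutation (latent-variable p value) and bootstrap
# (voxelwise bootstrap ratio).

#' Fit single-measure behavioral PLS
#'
#' Computes the voxelwise correlation vector `r` between brain values and
#' behavior, the singular value `||r||_2`, the unit-norm salience map
#' \eqn{r / \|r\|_2}, per-participant brain scores (projection of the
#' column-standardized brain matrix onto the salience), and the correlation
#' of brain scores with behavior. The salience sign is oriented so that the
#' brain-score-behavior correlation is nonnegative. For a single behavioral
#' variable this closed form is exactly the SVD of the 1 x voxels
#' correlation matrix.
#'
#' @param X Participants x voxels matrix (>= 4 rows).
#' @param y Behavior vector (nonconstant).
#' @return List with `salience`, `singular_value`, `brain_scores`,
#'   `r_brainscore_behavior`, `r` (unnormalized correlation vector) and
#'   `zero_var` (flag vector).
#' @export
fit_pls <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 participants")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  cc <- col_cor(X, y)
  if (cc$y_constant) stop("behavior is constant; PLS undefined")
  if (all(cc$zero_var)) stop("all voxels have zero variance; PLS undefined")
  r <- cc$r
  sv <- sqrt(sum(r^2))
  if (sv == 0) {
    stop("correlation vector is identically zero; salience undefined ",
         "(is the behavior orthogonal to every voxel in this sample?)")
  }
  salience <- r / sv
  # column-standardize X for the brain-score projection; zero-variance
  # columns contribute 0
  xm <- colMeans(X)
  Xc <- X - rep(xm, each = n)
  sx <- sqrt(colSums(Xc^2) / (n - 1))
  inv <- ifelse(sx > 0, 1 / sx, 0)
  brain_scores <- as.numeric(Xc %*% (salience * inv))
  r_bs <- if (stats::sd(brain_scores) > 0) stats::cor(brain_scores, y) else 0
  if (r_bs < 0) {
    salience <- -salience
    r <- -r
    brain_scores <- -brain_scores
    r_bs <- -r_bs
  }
  list(salience = salience, singular_value = sv, brain_scores = brain_scores,
       r_brainscore_behavior = r_bs, r = r, zero_var = cc$zero_var)
}

# Singular values under B random permutations of y, computed in blocks.
# Returns numeric vector of length n_perm.
perm_singular_values <- function(X, y, n_perm, rng_seed, block = 250L) {
  n <- nrow(X)
  yc <- y - mean(y)
  sy <- sum(yc^2)
  xm <- colMeans(X)
  Xc <- X - rep(xm, each = n)
  sx <- colSums(Xc^2)
  den <- sqrt(ifelse(sx > 0, sx, 1) * sy)
  set.seed(rng_seed)
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    P <- vapply(seq_len(b), function(j) yc[sample.int(n)], numeric(n))
    R <- crossprod(Xc, P) / den   # voxels x b, zero-variance rows are 0
    out[done + seq_len(b)] <- sqrt(colSums(R^2))
    done <- done + b
  }
  out
}

#' Permutation p value for the PLS latent variable
#'
#' Permutes the behavior vector uniformly, recomputes the singular value for
#' each permutation, and reports `p = (1 + #\{s_perm >= s_obs\}) / (1 + n_perm)`.
#' The add-one smoothing keeps p strictly positive (a raw proportion can
#' return 0, which breaks log-scale reporting).
#'
#' @param X Participants x voxels matrix.
#' @param y Behavior vector.
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Integer seed for the permutation stream.
#' @return List with `perm_p`, `s_obs` and `s_perm` (vector of permuted
#'   singular values).
#' @export
permutation_pvalue <- function(X, y, n_perm = 1000, rng_seed = 1L) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(X)
  cc <- col_cor(X, y)
  if (cc$y_constant) stop("behavior is constant; permutation test undefined")
  s_obs <- sqrt(sum(cc$r^2))
  s_perm <- perm_singular_values(X, y, n_perm, rng_seed)
  p <- (1 + sum(s_perm >= s_obs)) / (1 + n_perm)
  list(perm_p = p, s_obs = s_obs, s_perm = s_perm)
}

#' Bootstrap-ratio map
#'
#' Resamples participants with replacement (rows of `X` jointly with `y`),
#' recomputes the unnormalized voxelwise correlation vector per replicate
#' with its sign aligned to the observed vector (flipped when the inner
#' product with the observed vector is negative — the single-LV case of
#' procrustes alignment), and returns `bsr_v = r_obs_v / SD_boot(r*_v)`.
#' The ratio is computed on the unnormalized correlation vector rather than
#' the unit-norm salience: this decouples the per-voxel scale from the
#' singular value and matches "salience / SE" up to a common constant.
#' Replicates with constant `y` are redrawn (at most 10 retries each).
#'
#' @param X Participants x voxels matrix.
#' @param y Behavior vector.
#' @param n_boot Number of bootstrap replicates (default 1000, >= 2).
#' @param rng_seed Integer seed for the bootstrap stream.
#' @return List with `bsr` (vector), `se` (bootstrap SD of r*), `r_obs` and
#'   `flagged` (voxels with zero bootstrap SD, reported as bsr = 0).
#' @export
bootstrap_bsr <- function(X, y, n_boot = 1000, rng_seed = 1L) {
  stopifnot(n_boot >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  cc <- col_cor(X, y)
  if (cc$y_constant) stop("behavior is constant; bootstrap undefined")
  r_obs <- cc$r
  set.seed(rng_seed)
  s1 <- numeric(ncol(X))
  s2 <- numeric(ncol(X))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (stats::var(y[idx]) == 0) {
      tries <- tries + 1L
      if (tries > 10L) stop("persistent degenerate bootstrap replicates (constant behavior)")
      idx <- sample.int(n, n, replace = TRUE)
    }
    rs <- col_cor(X[idx, , drop = FALSE], y[idx])$r
    if (sum(rs * r_obs) < 0) rs <- -rs
    s1 <- s1 + rs
    s2 <- s2 + rs^2
  }
  se <- sqrt(pmax(0, (s2 - s1^2 / n_boot) / (n_boot - 1)))
  flagged <- se <= 0
  bsr <- ifelse(flagged, 0, r_obs / ifelse(se > 0, se, 1))
  list(bsr = bsr, se = se, r_obs = r_obs, flagged = flagged)
}

#' Run the full behavioral PLS analysis
#'
#' Bundles [fit_pls()], [permutation_pvalue()] and [bootstrap_bsr()] with
#' the conventional defaults of 1,000 permutations and 1,000 bootstrap
#' resamplings. Permutation and bootstrap use separate RNG streams derived
#' from `seed`, so the result is a pure function of its arguments.
#'
#' @param X Participants x voxels matrix.
#' @param y Behavior vector.
#' @param n_perm,n_boot Resampling settings (defaults 1000 each).
#' @param seed Integer master seed.
#' @return Object of class `pls_result`: `salience` (unit norm),
#'   `singular_value`, `brain_scores`, `r_brainscore_behavior`, `perm_p`,
#'   `bsr` (vector), `bsr_flagged`, `n_perm`, `n_boot`, `seed`.
#' @export
run_behavioral_pls <- function(X, y, n_perm = 1000, n_boot = 1000, seed = 1L) {
  fit <- fit_pls(X, y)
  perm <- permutation_pvalue(X, y, n_perm, derive_seed(seed, "perm"))
  boot <- bootstrap_bsr(X, y, n_boot, derive_seed(seed, "boot"))
  # orient the BSR map with the (possibly flipped) salience
  bsr <- boot$bsr * ifelse(sign(fit$r) * sign(boot$r_obs) < 0, -1, 1)
  structure(list(salience = fit$salience,
                 singular_value = fit$singular_value,
                 brain_scores = fit$brain_scores,
                 r_brainscore_behavior = fit$r_brainscore_behavior,
                 perm_p = perm$perm_p,
                 bsr = bsr,
                 bsr_flagged = boot$flagged,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(paste0("<pls_result> n=%d, singular value %.4g, ",
                     "r(brain score, behavior) = %.3f, perm p = %.4g ",
                     "(%d perms, %d bootstraps)\n"),
              length(x$brain_scores), x$singular_value,
              x$r_brainscore_behavior, x$perm_p, x$n_perm, x$n_boot))
  invisible(x)
}
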