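# Internal numeric helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with an arbitrary sequence of integer or character
#' tags into a new seed in `[0, 2^31 - 2]`. Used so that every stochastic
#' stage of the pipeline (cohort noise, each subsample draw, permutation and
#' bootstrap streams) gets its own deterministic stream: adding one stage
#' never perturbs another.
#'
#' @param seed Integer master seed.
#' @param ... Integer or character tags identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- list(...)
  # accumulate in double precision; modulus 2^31 - 1 keeps results in
  # 32-bit integer range (R integers are 32-bit)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in tags) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (t in as.numeric(tag)) {
      h <- (h * 48271 + t + 1) %% m
    }
  }
  as.integer(h)
}

# Columnwise Pearson correlation of each column of X with y.
# Returns list(r, zero_var): r has 0 at zero-variance columns, flagged in
# zero_var. Constant y is an error for callers that require it; here we
# return all-zero r with attribute so callers can decide.
col_cor <- function(X, y) {
  n <- nrow(X)
  yc <- y - mean(y)
  sy <- sum(yc^2)
  xm <- colMeans(X)
  Xc <- X - rep(xm, each = n)
  sx <- colSums(Xc^2)
  num <- as.vector(crossprod(Xc, yc))
  den <- sqrt(sx * sy)
  zero_var <- sx <= 0
  r <- ifelse(den > 0, num / den, 0)
  # numerical safety: clamp to [-1, 1]
  r <- pmin(1, pmax(-1, r))
  list(r = r, zero_var = zero_var, y_constant = sy <= 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
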