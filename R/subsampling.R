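# Non-overlapping, optionally stratified subsample draws of graded sizes.

#' Default subsample schedules
#'
#' The two schedules used in the experiments this package emulates. Each
#' entry is a subsample size and the number of pairwise-disjoint subsamples
#' drawn at that size.
#'
#' @param design `"dallas"` (n = 171 cohort: sizes 12x10, 24x7, 36x4, 48x3,
#'   60x2, 72x2, 84x2) or `"hcp"` (n = 865 cohort: 20, 40, 60, 80 with 10
#'   subsamples each, then 100x8, 120x7, 140x6, 160x5, 210x4, 280x3, 420x2).
#' @return A `data.frame` of class `subsample_schedule` with columns `size`
#'   and `n_subsamples`.
#' @export
default_schedule <- function(design = c("dallas", "hcp")) {
  design <- match.arg(design)
  sched <- switch(design,
    dallas = data.frame(size = c(12L, 24L, 36L, 48L, 60L, 72L, 84L),
                        n_subsamples = c(10L, 7L, 4L, 3L, 2L, 2L, 2L)),
    hcp = data.frame(size = c(20L, 40L, 60L, 80L, 100L, 120L, 140L, 160L,
                              210L, 280L, 420L),
                     n_subsamples = c(10L, 10L, 10L, 10L, 8L, 7L, 6L, 5L,
                                      4L, 3L, 2L)))
  subsample_schedule(sched$size, sched$n_subsamples)
}

#' Construct a subsample schedule
#'
#' @param size Integer vector of subsample sizes (strictly positive).
#' @param n_subsamples Integer vector, number of disjoint subsamples per size.
#' @return A `data.frame` of class `subsample_schedule`.
#' @export
subsample_schedule <- function(size, n_subsamples) {
  size <- as.integer(size); n_subsamples <- as.integer(n_subsamples)
  stopifnot(length(size) == length(n_subsamples),
            all(size > 0), all(n_subsamples > 0))
  structure(data.frame(size = size, n_subsamples = n_subsamples),
            class = c("subsample_schedule", "data.frame"))
}

#' Draw pairwise-disjoint subsamples at one size
#'
#' All subsamples of a given size contain different individuals (sampling
#' without replacement across subsamples); draws at different sizes use
#' independent streams of the master seed, so participants may recur across
#' sizes. With strata, each subsample contains exactly `size / n_strata`
#' members per stratum, keeping the stratum composition identical across all
#' subsamples of a size; `size` must be divisible by the number of strata.
#'
#' @param n_total Cohort size.
#' @param size Participants per subsample.
#' @param count Number of disjoint subsamples.
#' @param strata Optional factor of length `n_total`.
#' @param rng_seed Master integer seed; the per-(size, subsample) stream is
#'   derived from it, so adding another size never changes these draws.
#' @return Object of class `subsample_set`: list with `size`, `index_sets`
#'   (list of integer vectors, each sorted), `strata` and `seed`.
#' @export
draw_subsamples <- function(n_total, size, count, strata = NULL, rng_seed = 1L) {
  size <- as.integer(size); count <- as.integer(count)
  stopifnot(size >= 1, count >= 1)
  if (size * count > n_total) {
    stop(sprintf("infeasible: %d subsamples of %d need %d participants but only %d available",
                 count, size, size * count, n_total))
  }
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n_total) stop("strata must have length n_total")
    k <- nlevels(strata)
    if (size %% k != 0) {
      stop(sprintf("stratified draw needs size divisible by the %d strata (got size %d)", k, size))
    }
    per <- size %/% k
    counts <- table(strata)
    if (any(counts < per * count)) {
      short <- names(counts)[counts < per * count]
      stop(sprintf("infeasible: stratum %s has %s members but %d are needed",
                   paste(short, collapse = ","),
                   paste(counts[short], collapse = ","), per * count))
    }
  }
  sample_from <- function(x, k) x[sample.int(length(x), k)]  # avoids sample()'s scalar quirk
  pool <- seq_len(n_total)
  index_sets <- vector("list", count)
  for (j in seq_len(count)) {
    set.seed(derive_seed(rng_seed, "subsample", size, j))
    if (is.null(strata)) {
      picked <- sample_from(pool, size)
    } else {
      picked <- unlist(lapply(levels(strata), function(s) {
        sample_from(pool[strata[pool] == s], size %/% nlevels(strata))
      }))
    }
    index_sets[[j]] <- sort(as.integer(picked))
    pool <- setdiff(pool, picked)
  }
  structure(list(size = size, index_sets = index_sets,
                 strata = strata, seed = as.integer(rng_seed)),
            class = "subsample_set")
}

#' @export
print.subsample_set <- function(x, ...) {
  cat(sprintf("<subsample_set> %d disjoint subsamples of size %d\n",
              length(x$index_sets), x$size))
  invisible(x)
}

#' Serialize / restore subsample sets as JSON
#'
#' Records the size, seed and participant indices so a draw can be re-run or
#' audited exactly.
#'
#' @param x A `subsample_set`.
#' @param path Output (or input) JSON path.
#' @return `write_subsamples` returns `path` invisibly; `read_subsamples`
#'   returns a `subsample_set` (without strata, which are a property of the
#'   cohort).
#' @export
write_subsamples <- function(x, path) {
  stopifnot(inherits(x, "subsample_set"))
  jsonlite::write_json(list(size = x$size, seed = x$seed,
                            index_sets = x$index_sets),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_subsamples
#' @export
read_subsamples <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- obj$index_sets
  if (is.matrix(sets)) sets <- lapply(seq_len(nrow(sets)), function(i) as.integer(sets[i, ]))
  else sets <- lapply(sets, as.integer)
  structure(list(size = as.integer(obj$size), index_sets = sets,
                 strata = NULL, seed = as.integer(obj$seed)),
            class = "subsample_set")
}
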