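# Stability metrics across subsample maps: Spearman rho over unthresholded
# maps, Jaccard over thresholded voxel sets, penetration (overlap-count)
# maps, and per-size summaries.

#' Spearman rank correlation between two stat maps
#'
#' Pearson correlation of average-rank-transformed values over all masked
#' voxels (ties get average ranks). Computed over the full analysis mask,
#' unthresholded.
#'
#' @param map_a,map_b [stat_map]s (or bare numeric vectors) of equal length.
#' @return Spearman rho in `[-1, 1]`.
#' @export
spearman_rho <- function(map_a, map_b) {
  a <- if (inherits(map_a, "stat_map")) map_a$values else as.numeric(map_a)
  b <- if (inherits(map_b, "stat_map")) map_b$values else as.numeric(map_b)
  if (length(a) != length(b)) stop("maps differ in length")
  if (length(a) < 3) stop("need at least 3 voxels")
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("constant map: Spearman rho undefined")
  }
  stats::cor(ra, rb)
}

#' Jaccard index of two thresholded voxel sets
#'
#' `|A intersect B| / |A union B|`. When both sets are empty the 0/0 case is
#' defined as 0 ("nothing replicated" counts as zero stability) and the
#' result carries attribute `undefined = TRUE`.
#'
#' @param set_a,set_b Integer vectors of voxel indices (as returned by
#'   [threshold_map()]).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(as.integer(set_a)); set_b <- unique(as.integer(set_b))
  u <- length(union(set_a, set_b))
  if (u == 0) return(structure(0, undefined = TRUE))
  length(intersect(set_a, set_b)) / u
}

#' Dice coefficient of two thresholded voxel sets
#'
#' `2|A intersect B| / (|A| + |B|)`; provided as a convenience for
#' comparison with literature using Dice, equal to `2J / (1 + J)`.
#'
#' @inheritParams jaccard
#' @return Dice coefficient in `[0, 1]` (0 with attribute `undefined` when
#'   both sets are empty).
#' @export
dice <- function(set_a, set_b) {
  set_a <- unique(as.integer(set_a)); set_b <- unique(as.integer(set_b))
  s <- length(set_a) + length(set_b)
  if (s == 0) return(structure(0, undefined = TRUE))
  2 * length(intersect(set_a, set_b)) / s
}

#' Pairwise similarity table for a set of maps
#'
#' For every unordered pair of maps: Spearman rho on the unthresholded
#' values and Jaccard on the thresholded voxel sets (positive tail,
#' threshold 3 by default — flagged voxels are excluded by
#' [threshold_map()]).
#'
#' @param maps List of [stat_map]s sharing one mask.
#' @param threshold,tail Thresholding convention for the Jaccard sets.
#' @param size,method Optional labels recorded in the table.
#' @return `data.frame` with columns `size`, `method`, `map_a`, `map_b`,
#'   `rho`, `jaccard`, `overlap` (|A intersect B|), `jaccard_defined`.
#' @export
pairwise_similarity <- function(maps, threshold = 3, tail = "positive",
                                size = NA_integer_, method = NA_character_) {
  k <- length(maps)
  if (k < 2) stop("need at least 2 maps")
  lens <- vapply(maps, function(m) length(m$values), integer(1))
  if (length(unique(lens)) != 1) stop("maps do not share a mask")
  sets <- lapply(maps, threshold_map, threshold = threshold, tail = tail)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    jc <- jaccard(sets[[i]], sets[[j]])
    data.frame(size = size, method = method, map_a = i, map_b = j,
               rho = spearman_rho(maps[[i]], maps[[j]]),
               jaccard = as.numeric(jc),
               overlap = length(intersect(sets[[i]], sets[[j]])),
               jaccard_defined = !isTRUE(attr(jc, "undefined")))
  })
  do.call(rbind, rows)
}

#' Penetration (overlap-count) map
#'
#' Counts, per voxel, how many of the thresholded maps contain that voxel.
#' Voxels with a count below `min_reported` (default 2) are zeroed in the
#' reported map; raw counts are kept alongside. No clustering is applied to
#' the thresholded maps.
#'
#' @param maps List of [stat_map]s sharing one mask.
#' @param threshold,tail Thresholding convention.
#' @param min_reported Minimum overlap count reported (default 2).
#' @return Object of class `penetration_map`: `counts` (raw integer vector
#'   over masked voxels), `reported` (counts with values below
#'   `min_reported` set to 0), `n_maps`, `min_reported`.
#' @export
penetration <- function(maps, threshold = 3, tail = "positive",
                        min_reported = 2) {
  k <- length(maps)
  if (k < 2) stop("need at least 2 maps")
  lens <- vapply(maps, function(m) length(m$values), integer(1))
  if (length(unique(lens)) != 1) stop("maps do not share a mask")
  counts <- integer(lens[1])
  for (m in maps) {
    idx <- threshold_map(m, threshold = threshold, tail = tail)
    counts[idx] <- counts[idx] + 1L
  }
  reported <- ifelse(counts >= min_reported, counts, 0L)
  structure(list(counts = counts, reported = as.integer(reported),
                 n_maps = k, min_reported = as.integer(min_reported)),
            class = "penetration_map")
}

#' @export
print.penetration_map <- function(x, ...) {
  cat(sprintf("<penetration_map> %d maps; %d voxels with overlap >= %d (max %d)\n",
              x$n_maps, sum(x$reported > 0), x$min_reported, max(x$counts)))
  invisible(x)
}

#' Per-size overlap and similarity summary
#'
#' Averages the pairwise similarity table within each (size, method) cell:
#' mean/SD of rho and Jaccard, and the mean number of overlapping
#' above-threshold voxels.
#'
#' @param sim_table A `data.frame` from [pairwise_similarity()] (rows from
#'   several sizes/methods may be concatenated).
#' @return `data.frame` with one row per (size, method): `n_pairs`,
#'   `mean_rho`, `sd_rho`, `mean_jaccard`, `sd_jaccard`, `mean_overlap`.
#' @export
overlap_summary <- function(sim_table) {
  stopifnot(is.data.frame(sim_table), nrow(sim_table) >= 1)
  cells <- split(sim_table, list(sim_table$size, sim_table$method), drop = TRUE)
  rows <- lapply(cells, function(d) {
    data.frame(size = d$size[1], method = d$method[1], n_pairs = nrow(d),
               mean_rho = mean(d$rho), sd_rho = stats::sd(d$rho),
               mean_jaccard = mean(d$jaccard), sd_jaccard = stats::sd(d$jaccard),
               mean_overlap = mean(d$overlap))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}
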