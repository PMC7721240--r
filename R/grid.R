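#' Volume grid geometry
#'
#' A `volume_grid` records the shape of a 3D sampling grid, its voxel size in
#' mm, and the 4x4 affine mapping voxel indices (0-based, as in the NIfTI
#' convention) to mm coordinates.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm Numeric vector of length 3, mm per voxel. Ignored if
#'   `affine` is supplied (then derived from the affine columns).
#' @param affine 4x4 numeric matrix, or `NULL` to build a diagonal affine
#'   centred on the grid.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(20, 20, 20), voxel_size_mm = c(3, 3, 3))
#' @export
volume_grid <- function(shape, voxel_size_mm = c(3, 3, 3), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop("shape must be three integers, all >= 1")
  }
  if (is.null(affine)) {
    voxel_size_mm <- as.numeric(voxel_size_mm)
    stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
    # centre the grid on the origin, as for a standard-space bounding box
    origin <- -voxel_size_mm * (shape - 1) / 2
    affine <- rbind(cbind(diag(voxel_size_mm), origin), c(0, 0, 0, 1))
    dimnames(affine) <- NULL
  } else {
    affine <- unname(as.matrix(affine))
    if (!all(dim(affine) == c(4, 4))) stop("affine must be a 4x4 matrix")
    if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
    voxel_size_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "volume_grid")
}

#' Default analysis grid
#'
#' 20 x 20 x 20 voxels at 3 mm isotropic (the working resolution of the
#' analyses this package emulates): about 8,000 voxels, small enough for
#' desk-scale resampling loops while leaving room for spatial overlap
#' statistics.
#'
#' @return A [volume_grid].
#' @export
default_grid <- function() volume_grid(c(20L, 20L, 20L), c(3, 3, 3))

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels at %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Voxel mask over a grid
#'
#' @param grid A [volume_grid].
#' @param in_mask Logical array with `dim == grid$shape` (or a logical/numeric
#'   3D array; nonzero = inside). `NULL` means all voxels in-mask.
#' @return An object of class `voxel_mask` with fields `grid`, `in_mask`
#'   (logical array) and `n_voxels`.
#' @export
voxel_mask <- function(grid, in_mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(in_mask)) {
    in_mask <- array(TRUE, dim = grid$shape)
  } else {
    if (!all(dim(in_mask) == grid$shape)) stop("mask dimensions do not match grid shape")
    in_mask <- array(as.logical(in_mask != 0 & !is.na(in_mask)), dim = grid$shape)
  }
  n <- sum(in_mask)
  if (n < 1) stop("mask must contain at least one voxel")
  structure(list(grid = grid, in_mask = in_mask, n_voxels = as.integer(n)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d of %d voxels in mask\n",
              x$n_voxels, prod(x$grid$shape)))
  invisible(x)
}

#' Extract masked voxels as a vector
#'
#' Voxel order is fixed for the whole pipeline: ascending linear array index
#' with the first axis fastest (R's native array layout). Every map produced
#' by this package shares that order, so vectors from different stages are
#' directly comparable.
#'
#' @param volume 3D numeric array on the mask's grid.
#' @param mask A [voxel_mask].
#' @return Numeric vector of length `mask$n_voxels`.
#' @seealso [devectorize()]
#' @export
vectorize <- function(volume, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(dim(volume)) != 3 || !all(dim(volume) == mask$grid$shape)) {
    stop("volume dimensions do not match mask grid")
  }
  as.numeric(volume[mask$in_mask])
}

#' Restore a masked vector to a 3D volume
#'
#' Out-of-mask voxels are filled with `NaN` so that downstream thresholding
#' can never pick them up.
#'
#' @param values Numeric vector of length `mask$n_voxels`.
#' @param mask A [voxel_mask].
#' @param fill Fill value outside the mask (default `NaN`).
#' @return 3D numeric array.
#' @export
devectorize <- function(values, mask, fill = NaN) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(values) != mask$n_voxels) {
    stop(sprintf("expected %d values, got %d", mask$n_voxels, length(values)))
  }
  out <- array(fill, dim = mask$grid$shape)
  out[mask$in_mask] <- values
  out
}
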