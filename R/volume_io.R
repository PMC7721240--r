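# NIfTI input/output and cohort tables. All volume I/O goes through RNifti.

#' Load a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param expected_grid Optional [volume_grid]; if given, the file's grid must
#'   match (shape exactly, affine within `tol` mm).
#' @param tol Affine tolerance in mm when checking `expected_grid`.
#' @return A list with `data` (3D array, NaN preserved) and `grid`.
#' @export
load_volume <- function(path, expected_grid = NULL, tol = 1e-4) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3) stop("expected a 3D volume, got ", length(d), " dimensions: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  grid <- volume_grid(d, affine = aff)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid, tol)) {
    stop("grid mismatch: ", path, " has shape ", paste(d, collapse = "x"),
         ", expected ", paste(expected_grid$shape, collapse = "x"),
         " (or affines differ beyond ", tol, " mm)")
  }
  list(data = array(as.numeric(img), dim = d), grid = grid)
}

#' Write a 3D array as a NIfTI volume
#'
#' Data are written as 32-bit float; the grid's affine is written as the
#' sform/qform as given.
#'
#' @param volume 3D numeric array.
#' @param grid [volume_grid] describing the geometry.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype (default `"float"`; use `"int16"` for
#'   integer count maps).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, grid, path, datatype = "float") {
  stopifnot(inherits(grid, "volume_grid"))
  if (!all(dim(volume) == grid$shape)) stop("volume dimensions do not match grid")
  img <- RNifti::asNifti(array(as.numeric(volume), dim = grid$shape))
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load a binary mask volume
#'
#' @inheritParams load_volume
#' @return A [voxel_mask]. Nonzero, non-NA voxels are in-mask.
#' @export
load_mask <- function(path, expected_grid = NULL) {
  v <- load_volume(path, expected_grid)
  voxel_mask(v$grid, v$data)
}

#' Read a cohort table
#'
#' Reads a delimited text file (CSV or TSV, sniffed from the extension or
#' first line) holding one row per participant: an id column, a behavioral
#' score, and nuisance covariate columns. Column names are configurable so
#' arbitrary study tables can be ingested.
#'
#' @param path Path to a delimited file with a header row.
#' @param id_col,behavior_col Names of the id and behavior columns.
#' @param covariate_cols Character vector of covariate column names
#'   (default `c("age", "fd")`).
#' @param stratum_col Optional name of a categorical stratum column; `NULL`
#'   (default) means use the column named `"stratum"` if present, else none.
#' @return A `data.frame` of class `cohort_table` with columns
#'   `participant_id`, `behavior`, one column per covariate, and optionally
#'   `stratum` (factor). Row order is preserved.
#' @export
read_cohort_table <- function(path, id_col = "participant_id",
                              behavior_col = "behavior",
                              covariate_cols = c("age", "fd"),
                              stratum_col = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(id_col, behavior_col, covariate_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate participant ids in cohort table")
  behavior <- raw[[behavior_col]]
  if (!is.numeric(behavior)) stop("behavior column '", behavior_col, "' is not numeric")
  if (anyNA(behavior)) stop("missing behavior values are not allowed")
  out <- data.frame(participant_id = ids, behavior = as.numeric(behavior),
                    stringsAsFactors = FALSE)
  for (cc in covariate_cols) {
    if (!is.numeric(raw[[cc]])) stop("covariate column '", cc, "' is not numeric")
    out[[cc]] <- as.numeric(raw[[cc]])
  }
  if (is.null(stratum_col) && "stratum" %in% names(raw)) stratum_col <- "stratum"
  if (!is.null(stratum_col)) {
    if (!stratum_col %in% names(raw)) stop("stratum column '", stratum_col, "' not found")
    out$stratum <- factor(raw[[stratum_col]])
  }
  attr(out, "covariate_cols") <- covariate_cols
  class(out) <- c("cohort_table", "data.frame")
  out
}
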