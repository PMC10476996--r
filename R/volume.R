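#' @importFrom Matrix sparseMatrix t crossprod
#' @importFrom stats quantile rnorm runif median setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Axis convention used throughout the package: arrays are indexed
# [slice, row, column], slice axis running inferior -> superior.
# `spacing` and `origin` follow the same (slice, row, column) order, in mm.

#' Image volume container
#'
#' A 3D scalar grid (Hounsfield units or normalized intensities) with
#' per-axis voxel spacing and physical origin. Arrays are stored in
#' `(slice, row, column)` order with the slice axis running
#' inferior to superior; `spacing` and `origin` use the same axis order
#' and are expressed in millimetres.
#'
#' @param voxels 3D numeric array in `(slice, row, column)` order.
#' @param spacing numeric length-3, voxel spacing in mm, all `> 0`.
#' @param origin numeric length-3, physical position (mm) of the first voxel.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (length(voxels) == 0L) stop("`voxels` must be non-empty")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axis_order = "slice,row,col"),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d (slice,row,col), spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.6g, %.6g], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Named binary structure
#'
#' A single radiotherapy structure: free-text name plus a binary 3D mask
#' congruent with its paired [image_volume()] grid.
#'
#' @param name character scalar, the structure name as stored.
#' @param mask 3D array with values in `{0, 1}` (logical accepted).
#' @return An object of class `named_structure`.
#' @export
named_structure <- function(name, mask) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("`name` must be a character scalar")
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) stop("`mask` values must lie in {0, 1}")
  storage.mode(mask) <- "integer"
  structure(list(name = name, mask = mask), class = "named_structure")
}

#' Structure set container
#'
#' Named collection of binary masks sharing one grid, with the body
#' structure (named `"BODY"` or `"External"`) optionally designated.
#'
#' @param patient_id opaque patient identifier.
#' @param structures list of [named_structure()] objects on one grid.
#' @param body_index integer index of the body structure, or `NA`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(patient_id, structures, body_index = NA_integer_) {
  if (!is.list(structures) ||
      !all(vapply(structures, inherits, TRUE, "named_structure")))
    stop("`structures` must be a list of named_structure objects")
  if (length(structures) > 1L) {
    d0 <- dim(structures[[1L]]$mask)
    same <- vapply(structures, function(s) identical(dim(s$mask), d0), TRUE)
    if (!all(same)) stop("all masks in a structure set must share one grid")
  }
  if (!is.na(body_index)) {
    body_index <- as.integer(body_index)
    if (body_index < 1L || body_index > length(structures))
      stop("`body_index` out of range")
  }
  structure(list(patient_id = as.character(patient_id),
                 structures = structures,
                 body_index = body_index),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> patient '%s', %d structures%s\n",
              x$patient_id, length(x$structures),
              if (is.na(x$body_index)) "" else
                sprintf(", body = '%s'", x$structures[[x$body_index]]$name)))
  for (s in x$structures) cat("  -", s$name, "\n")
  invisible(x)
}

#' Structure names of a structure set
#' @param ss a [structure_set()].
#' @return character vector of structure names, in file order.
#' @export
structure_names <- function(ss) {
  vapply(ss$structures, function(s) s$name, character(1))
}

# Tight bounding box of a binary 3D mask; list of per-axis index ranges.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  lapply(1:3, function(a) range(idx[, a]))
}

# Indices (along slice axis) of 2D slices containing any nonzero voxel.
nonzero_slices <- function(mask) {
  which(apply(mask != 0, 1L, any))
}
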