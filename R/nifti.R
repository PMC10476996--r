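# Minimal NIfTI-1 codec.
#
# The package's canonical on-disk format is NIfTI-1 (.nii / .nii.gz).
# No NIfTI reader ships with the installed R stack, so a small
# single-file codec is provided here. It writes little-endian NIfTI-1
# with an sform diagonal affine and reads back the subset it writes
# (plus the common scalar datatypes). Internal arrays are
# (slice, row, col); NIfTI stores x (= column) fastest, so data are
# permuted on the way in and out. Orientation codes beyond the diagonal
# affine are not interpreted.

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume or mask to NIfTI-1
#'
#' @param data an [image_volume()], a [named_structure()], or a 3D array
#'   in `(slice, row, col)` order.
#' @param path output path; `.nii` or `.nii.gz`.
#' @param spacing,origin used when `data` is a bare array; otherwise
#'   taken from the object (masks carry no geometry of their own, so
#'   pass the paired volume's spacing/origin for masks).
#' @param datatype NIfTI datatype code: 4 (int16), 2 (uint8),
#'   16 (float32) or 64 (float64). Default: 64 for intensity data,
#'   2 for masks.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = NULL, origin = NULL,
                        datatype = NULL) {
  if (inherits(data, "image_volume")) {
    arr <- data$voxels
    spacing <- data$spacing; origin <- data$origin
    if (is.null(datatype)) datatype <- 64L
  } else if (inherits(data, "named_structure")) {
    arr <- data$mask
    if (is.null(spacing)) stop("mask writing needs the grid `spacing`")
    if (is.null(origin)) origin <- c(0, 0, 0)
    if (is.null(datatype)) datatype <- 2L
  } else {
    arr <- data
    if (is.null(spacing)) stop("array writing needs `spacing`")
    if (is.null(origin)) origin <- c(0, 0, 0)
    if (is.null(datatype)) datatype <- 64L
  }
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  d <- dim(arr)
  # (slice,row,col) -> (col,row,slice): x fastest on disk
  out <- aperm(arr, c(3L, 2L, 1L))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)
  wi32(348L)                      # sizeof_hdr
  wpad(36L)                       # data_type, db_name, extents, session_error,
                                  # regular, dim_info
  wi16(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L))  # dim[8]
  wpad(14L)                       # intent_p1..p3, intent_code
  wi16(datatype)                  # datatype
  wi16(dt$size * 8L)              # bitpix
  wi16(0L)                        # slice_start
  wf32(c(1, spacing[3], spacing[2], spacing[1], 0, 0, 0, 0))  # pixdim[8]
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0L); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  wf32(c(0, 0))                   # cal_max, cal_min
  wf32(c(0, 0)); wi32(c(0L, 0L))  # slice_duration, toffset, glmax, glmin
  wpad(104L)                      # descrip[80] + aux_file[24]
  wi16(0L); wi16(1L)              # qform_code = 0, sform_code = 1
  wf32(rep(0, 6))                 # quatern_b/c/d, qoffset_x/y/z
  wf32(c(spacing[3], 0, 0, origin[3]))  # srow_x
  wf32(c(0, spacing[2], 0, origin[2]))  # srow_y
  wf32(c(0, 0, spacing[1], origin[1]))  # srow_z
  wpad(16L)                       # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  writeBin(raw(1L), con)          # magic terminator
  wpad(4L)                        # extension flag
  v <- as.vector(out)
  if (dt$what == "integer") {
    writeBin(as.integer(round(v)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array, `(slice, row, col)` order),
#'   `spacing` and `origin` (mm, same axis order).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  ri16 <- function(off, n) readBin(hdr[(off + 1L):(off + 2L * n)], "integer",
                                   n = n, size = 2L, endian = "little")
  ri32 <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)], "integer",
                                   n = n, size = 4L, endian = "little")
  rf32 <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)], "double",
                                   n = n, size = 4L, endian = "little")
  if (ri32(0L, 1L) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- ri16(40L, 8L)
  if (dims[1L] < 3L || any(dims[5:8] > 1L))
    stop("only 3D NIfTI volumes are supported: ", path)
  nx <- dims[2L]; ny <- dims[3L]; nz <- dims[4L]
  datatype <- ri16(70L, 1L)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rf32(76L, 8L)
  vox_offset <- rf32(108L, 1L)
  scl_slope <- rf32(112L, 1L); scl_inter <- rf32(116L, 1L)
  sform_code <- ri16(254L, 1L)
  srow <- matrix(rf32(280L, 12L), nrow = 3L, byrow = TRUE)
  if (vox_offset > 352) readBin(con, "raw", n = as.integer(vox_offset) - 352L)
  n <- nx * ny * nz
  v <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
               signed = dt$signed)
  if (length(v) != n) stop("truncated NIfTI data: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr <- aperm(array(v, c(nx, ny, nz)), c(3L, 2L, 1L))
  if (sform_code > 0L) {
    spacing <- c(srow[3L, 3L], srow[2L, 2L], srow[1L, 1L])
    origin <- c(srow[3L, 4L], srow[2L, 4L], srow[1L, 4L])
  } else {
    spacing <- c(pixdim[4L], pixdim[3L], pixdim[2L])
    origin <- c(0, 0, 0)
  }
  list(data = arr, spacing = abs(spacing), origin = origin)
}
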