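# Grid resampling.
#
# Intensity volumes are resampled with separable quadratic (order-2)
# B-spline interpolation: a recursive prefilter per axis (single pole
# z = sqrt(8) - 3, mirror boundary) followed by evaluation of the
# 3-tap quadratic B-spline kernel. Interpolation is exact at source
# grid points. Masks use nearest-neighbor lookup and stay binary.
#
# Output grid convention: n_out = round(n_in * sp_in / sp_out) along
# each axis (at least 1), first voxel center coincident with the
# source origin, so the physical extent is preserved to within one
# output voxel.

.bspline2_pole <- sqrt(8) - 3

# In-place-style causal/anticausal prefilter of a matrix along rows
# (i.e. each column filtered independently). `x` is (n x m).
bspline2_prefilter_cols <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(x)
  z <- .bspline2_pole
  lambda <- (1 - z) * (1 - 1 / z)
  x <- x * lambda
  # causal init, mirror boundary; exact closed form for short signals
  horizon <- ceiling(log(1e-14) / log(abs(z)))
  if (horizon < n) {
    zk <- z^(seq_len(horizon - 1L))
    c0 <- x[1L, , drop = FALSE] + zk %*% x[2L:horizon, , drop = FALSE]
  } else {
    k <- seq_len(n - 2L)
    zk <- z^k + z^(2L * n - 2L - k)
    c0 <- x[1L, , drop = FALSE] + z^(n - 1L) * x[n, , drop = FALSE]
    if (n > 2L) c0 <- c0 + zk %*% x[2L:(n - 1L), , drop = FALSE]
    c0 <- c0 / (1 - z^(2L * n - 2L))
  }
  x[1L, ] <- c0
  for (k in 2:n) x[k, ] <- x[k, ] + z * x[k - 1L, ]
  x[n, ] <- (z / (z * z - 1)) * (z * x[n - 1L, ] + x[n, ])
  for (k in (n - 1L):1L) x[k, ] <- z * (x[k + 1L, ] - x[k, ])
  x
}

# Mirror-reflect 0-based indices into [0, n-1].
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- abs(i) %% p
  ifelse(i >= n, p - i, i)
}

# Sparse (n_out x n_in) quadratic B-spline evaluation matrix for
# 0-based source coordinates `t`.
bspline2_eval_matrix <- function(t, n_in) {
  base <- floor(t + 0.5)
  f <- t - base
  w <- cbind((f - 0.5)^2 / 2, 0.75 - f^2, (f + 0.5)^2 / 2)
  idx <- cbind(base - 1, base, base + 1)
  rows <- rep(seq_along(t), 3L)
  cols <- mirror_index(as.vector(idx), n_in) + 1L
  Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(w),
                       dims = c(length(t), n_in))
}

# Multiply a matrix `A` (n_out x n_in) along axis `axis` of 3D array.
apply_axis <- function(arr, A, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- as.matrix(A %*% m)
  d2 <- d; d2[axis] <- nrow(A)
  aperm(array(out, c(nrow(A), d[perm[2L]], d[perm[3L]])), order(perm))
}

#' Resample a volume to a target spacing
#'
#' @param volume an [image_volume()], or a bare 3D array with `spacing`
#'   supplied.
#' @param target_spacing numeric length-3 target spacing in mm,
#'   `(slice, row, col)` order.
#' @param mode `"intensity"` (quadratic B-spline) or `"mask"`
#'   (nearest neighbor; output stays binary).
#' @param spacing source spacing when `volume` is a bare array.
#' @return an [image_volume()] (or bare array, matching the input) on
#'   the resampled grid.
#' @export
resample <- function(volume, target_spacing, mode = c("intensity", "mask"),
                     spacing = NULL) {
  mode <- match.arg(mode)
  is_vol <- inherits(volume, "image_volume")
  arr <- if (is_vol) volume$voxels else volume
  spacing <- if (is_vol) volume$spacing else as.numeric(spacing)
  origin <- if (is_vol) volume$origin else c(0, 0, 0)
  if (is.null(spacing) || length(spacing) != 3L)
    stop("source `spacing` required")
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  d <- dim(arr)
  if (isTRUE(all.equal(spacing, target_spacing))) {
    return(if (is_vol) volume else arr)
  }
  n_out <- pmax(1L, as.integer(round(d * spacing / target_spacing)))
  coords <- lapply(1:3, function(a)
    (seq_len(n_out[a]) - 1L) * target_spacing[a] / spacing[a])
  if (mode == "mask") {
    idx <- lapply(1:3, function(a)
      pmin(d[a], pmax(1L, as.integer(round(coords[[a]])) + 1L)))
    out <- arr[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    storage.mode(out) <- storage.mode(arr)
  } else {
    out <- arr
    storage.mode(out) <- "double"
    for (a in 1:3) {
      if (d[a] >= 2L) {
        perm <- c(a, setdiff(1:3, a))
        m <- matrix(aperm(out, perm), nrow = dim(out)[a])
        m <- bspline2_prefilter_cols(m)
        dp <- dim(out)[perm]
        out <- aperm(array(m, dp), order(perm))
      }
      A <- bspline2_eval_matrix(coords[[a]], d[a])
      out <- apply_axis(out, A, a)
    }
  }
  if (is_vol) image_volume(out, target_spacing, origin) else out
}
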