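# Contour tracing and scan-line rasterization.
#
# Masks are traced per slice at the 0.5 iso-level (grDevices::contourLines
# on a zero-padded slice so boundaries always close) and rasterized back
# with an even-odd scan-line fill over voxel centers. Because the traced
# boundary runs halfway between voxel centers, no voxel center ever lies
# exactly on a contour and the round trip is stable.

# Trace closed planar contours from a binary mask. Returns a list of
# polygons: list(x = col mm, y = row mm, z = slice position mm).
mask_to_contours <- function(mask, spacing, origin) {
  d <- dim(mask)
  rows_mm <- origin[2L] + (-1:d[2L]) * spacing[2L]
  cols_mm <- origin[3L] + (-1:d[3L]) * spacing[3L]
  out <- list()
  for (k in nonzero_slices(mask)) {
    padded <- matrix(0, d[2L] + 2L, d[3L] + 2L)
    padded[2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask[k, , ]
    cl <- grDevices::contourLines(rows_mm, cols_mm, padded, levels = 0.5)
    z <- origin[1L] + (k - 1L) * spacing[1L]
    for (p in cl) {
      # contourLines: x follows the first matrix index (rows), y the second
      n <- length(p$x)
      # drop duplicated closing vertex if present; CLOSED_PLANAR is implicit
      if (n > 1L && p$x[1L] == p$x[n] && p$y[1L] == p$y[n]) {
        p$x <- p$x[-n]; p$y <- p$y[-n]
      }
      out[[length(out) + 1L]] <- list(x = p$y, y = p$x, z = z)
    }
  }
  out
}

# Rasterize closed planar contours (list(x = col mm, y = row mm, z = mm))
# onto a (slice, row, col) grid. Overlapping polygons on one slice
# combine with even-odd parity, so holes are supported.
contours_to_mask <- function(polys, dims, spacing, origin) {
  mask <- array(0L, dims)
  row_centers <- origin[2L] + (seq_len(dims[2L]) - 1L) * spacing[2L]
  col_centers <- origin[3L] + (seq_len(dims[3L]) - 1L) * spacing[3L]
  for (p in polys) {
    k <- as.integer(round((p$z - origin[1L]) / spacing[1L])) + 1L
    if (k < 1L || k > dims[1L])
      stop("contour slice position outside the CT grid")
    filled <- fill_polygon(p$x, p$y, col_centers, row_centers)
    mask[k, , ] <- xor(mask[k, , ] > 0L, filled) * 1L
  }
  mask
}

# Even-odd scan-line fill of one polygon. Returns an (nrow x ncol)
# integer matrix over the given voxel-center coordinates.
fill_polygon <- function(px, py, col_centers, row_centers) {
  n <- length(px)
  x1 <- px; y1 <- py
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  out <- matrix(FALSE, length(row_centers), length(col_centers))
  rng <- range(py)
  for (ri in which(row_centers >= rng[1L] & row_centers <= rng[2L])) {
    y0 <- row_centers[ri]
    crosses <- (y1 <= y0 & y2 > y0) | (y2 <= y0 & y1 > y0)
    if (!any(crosses)) next
    t <- (y0 - y1[crosses]) / (y2[crosses] - y1[crosses])
    xs <- sort(x1[crosses] + t * (x2[crosses] - x1[crosses]))
    out[ri, ] <- findInterval(col_centers, xs) %% 2L == 1L
  }
  out * 1L
}
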