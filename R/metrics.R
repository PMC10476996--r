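# Classification and geometric evaluation metrics.

#' Classification report
#'
#' Per-class precision, recall and F1 with macro (unweighted) and
#' weighted (support-weighted) aggregates, plain accuracy, macro
#' per-label accuracy (the unweighted mean of per-class recall, i.e.
#' balanced accuracy) and the vocabulary-ordered confusion matrix.
#' Zero-division cases (a class never predicted, or absent from the
#' truth) are reported as 0 and flagged.
#'
#' @param truth,predicted equal-length character vectors of labels.
#' @param vocabulary ordered class vocabulary; every label must be in
#'   it.
#' @return a `metrics_report` list: `per_class` data frame (precision,
#'   recall, f1, support, zero-division flags), `macro` and `weighted`
#'   aggregates, `accuracy`, `macro_label_accuracy`, `confusion`
#'   (counts) and `confusion_normalized` (row-normalized).
#' @export
classification_report <- function(truth, predicted, vocabulary) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  bad <- setdiff(unique(c(truth, predicted)), vocabulary)
  if (length(bad)) stop("labels outside vocabulary: ",
                        paste(bad, collapse = ", "))
  tf <- factor(truth, levels = vocabulary)
  pf <- factor(predicted, levels = vocabulary)
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  support <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  per_class <- data.frame(
    class = vocabulary,
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.numeric(support),
    precision_undefined = pred_n == 0,
    recall_undefined = support == 0,
    row.names = NULL)
  w <- support / sum(support)
  norm <- cm / ifelse(support > 0, support, 1)
  structure(list(
    per_class = per_class,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    accuracy = sum(tp) / length(truth),
    macro_label_accuracy = mean(recall),
    confusion = unclass(cm),
    confusion_normalized = unclass(norm)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n")
  df <- x$per_class
  df[c("precision", "recall", "f1")] <-
    round(df[c("precision", "recall", "f1")], digits)
  print(df[c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  cat(sprintf("accuracy %.4f | macro label accuracy %.4f\n",
              x$accuracy, x$macro_label_accuracy))
  cat(sprintf("macro P/R/F1 %.4f/%.4f/%.4f | weighted %.4f/%.4f/%.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"],
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined as DSC 1 with
#' attribute `"both_empty"` set.
#'
#' @param a,b congruent binary 3D arrays.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("mask grids differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# Boundary voxels (6-connectivity): mask voxels with at least one of
# the six face neighbors outside the mask or outside the volume.
surface_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_all <- function(ax, k) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    idx_src[[ax]] <- max(1L, 1L - k):min(n, n - k)
    idx_dst[[ax]] <- idx_src[[ax]] + k
    out[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
      m[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
    out
  }
  for (ax in 1:3) for (k in c(-1L, 1L))
    interior <- interior & shift_all(ax, k)
  which(m & !interior, arr.ind = TRUE)
}

# Physical-space (mm) coordinates of surface voxels.
surface_points <- function(mask, spacing) {
  idx <- surface_voxels(mask)
  if (nrow(idx) == 0L) stop("mask is empty")
  sweep(idx - 1, 2L, spacing, `*`)
}

# For each point in `p` (n x 3 mm), distance to the nearest point in
# `q`, computed in column chunks to bound memory.
nearest_distances <- function(p, q, chunk = 512L) {
  qn <- rowSums(q * q)
  out <- numeric(nrow(p))
  for (i0 in seq(1L, nrow(p), by = chunk)) {
    i1 <- min(nrow(p), i0 + chunk - 1L)
    pp <- p[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(pp * pp), qn, `+`) - 2 * pp %*% Matrix::t(q)
    out[i0:i1] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

surface_distance_sets <- function(a, b, spacing) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("mask grids differ")
  if (sum(a) == 0L || sum(b) == 0L)
    stop("surface distances are undefined for an empty mask")
  pa <- surface_points(a, spacing)
  pb <- surface_points(b, spacing)
  list(ab = nearest_distances(pa, pb), ba = nearest_distances(pb, pa))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation) of the pooled symmetric
#' surface-to-surface distance distribution. Surfaces are boundary
#' voxels under 6-connectivity; distances are between voxel centers in
#' physical mm.
#'
#' @param a,b congruent non-empty binary masks.
#' @param spacing voxel spacing in mm, `(slice, row, col)`.
#' @param percentile percentile in `[0, 100]`, default 95.
#' @return distance in mm.
#' @export
hd95 <- function(a, b, spacing, percentile = 95) {
  d <- surface_distance_sets(a, b, spacing)
  as.numeric(quantile(c(d$ab, d$ba), percentile / 100, type = 7))
}

#' Symmetric mean surface distance (mm)
#'
#' Mean of the two directed mean nearest-surface distances.
#'
#' @inheritParams hd95
#' @return distance in mm.
#' @export
msd <- function(a, b, spacing) {
  d <- surface_distance_sets(a, b, spacing)
  (mean(d$ab) + mean(d$ba)) / 2
}

#' Truncate a prediction above the ground truth
#'
#' Removes predicted voxels in slices strictly superior to the most
#' superior non-empty ground-truth slice; everything else is unchanged.
#'
#' @param prediction,ground_truth congruent binary masks; ground truth
#'   non-empty.
#' @return truncated prediction mask.
#' @export
truncate_superior <- function(prediction, ground_truth) {
  p <- as_mask_array(prediction); g <- as_mask_array(ground_truth)
  if (!identical(dim(p), dim(g))) stop("mask grids differ")
  nz <- nonzero_slices(g)
  if (length(nz) == 0L) stop("ground truth is empty")
  top <- max(nz)
  if (top < dim(p)[1L]) p[(top + 1L):dim(p)[1L], , ] <- 0L
  p
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped. For n <= 12 retained pairs the null
#' distribution is enumerated exactly over all 2^n sign assignments
#' (ties in |difference| get average ranks); for larger n the normal
#' approximation with continuity and tie corrections is used.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `p.value`
#'   (two-sided), `n` (pairs retained) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; no signal to test")
  if (n < 5L) warning("fewer than 5 nonzero pairs; the test has almost ",
                      "no power", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_v <- as.vector(signs %*% r)
    p_le <- mean(null_v <= v + 1e-9)
    p_ge <- mean(null_v >= v - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p.value = p, n = n, method = method)
}
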