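# Shared test utilities: independent brute-force oracles and tiny
# fixture builders. Oracles are deliberately written as plain loops,
# independent of the package's vectorized implementations.

# All-pairs brute-force surface-distance oracle (6-connectivity
# boundary, voxel centers in mm).
oracle_surface <- function(mask) {
  d <- dim(mask)
  pts <- NULL
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (mask[s, r, cc] == 0) next
    boundary <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      n <- c(s, r, cc) + off
      if (any(n < 1) || any(n > d) || mask[n[1], n[2], n[3]] == 0) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) pts <- rbind(pts, c(s, r, cc))
  }
  pts
}

oracle_distances <- function(pa, pb, spacing) {
  out <- numeric(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    best <- Inf
    for (j in seq_len(nrow(pb))) {
      dmm <- (pa[i, ] - pb[j, ]) * spacing
      best <- min(best, sqrt(sum(dmm * dmm)))
    }
    out[i] <- best
  }
  out
}

oracle_hd95 <- function(a, b, spacing) {
  pa <- oracle_surface(a); pb <- oracle_surface(b)
  pooled <- c(oracle_distances(pa, pb, spacing),
              oracle_distances(pb, pa, spacing))
  as.numeric(quantile(pooled, 0.95, type = 7))
}

oracle_msd <- function(a, b, spacing) {
  pa <- oracle_surface(a); pb <- oracle_surface(b)
  (mean(oracle_distances(pa, pb, spacing)) +
     mean(oracle_distances(pb, pa, spacing))) / 2
}

oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    na <- na + (a[i] != 0); nb <- nb + (b[i] != 0)
    inter <- inter + (a[i] != 0 && b[i] != 0)
  }
  2 * inter / (na + nb)
}

# Random connected-ish blob mask on a small grid.
random_blob <- function(dims, seed) {
  set.seed(seed)
  ctr <- 1 + (dims - 1) * runif(3, 0.3, 0.7)
  semi <- pmax(1.2, dims * runif(3, 0.15, 0.35))
  m <- array(0L, dims)
  for (s in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      v <- sum(((c(s, r, cc) - ctr) / semi)^2)
      if (v <= 1) m[s, r, cc] <- 1L
    }
  m
}

# Tiny labelled classifier samples on a small grid: class patterns are
# distinct AddMap blobs; `n_per_class` samples per class with noise.
tiny_samples <- function(n_per_class = 4L, grid = c(8L, 8L, 6L),
                         vocabulary = c("A", "B", "Other"), seed = 1L) {
  set.seed(seed)
  dims <- c(grid[3L], grid[1L], grid[2L])     # (s, r, c)
  out <- list(); k <- 0L
  for (ci in seq_along(vocabulary)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      am <- array(0, dims)
      base <- switch(ci, 1L, 3L, 5L)
      am[2:5, base:(base + 2L), 2:5] <- 0.5
      am[3:4, base:(base + 1L), 3:4] <- 1
      ct <- array(rnorm(prod(dims), mean = ci, sd = 0.3), dims)
      out[[k]] <- classifier_sample(ct, am, name = paste0("s", k),
                                    label = vocabulary[ci],
                                    patient_id = sprintf("p%02d", k))
    }
  }
  out
}
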