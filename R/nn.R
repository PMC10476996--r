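# Compact neural-network engine.
#
# No deep-learning framework exists in the installed R stack, so the
# desk-scale networks are built from first principles: every 3D
# convolution (zero-padded "same", arbitrary stride) is precomputed as
# a sparse im2col gather matrix, turning forward and backward passes
# into sparse-dense matrix products handled by Matrix/BLAS. Layouts:
# a batch is a dense matrix (features x B); a feature vector is
# channel-major (all voxels of channel 1, then channel 2, ...), voxels
# in R array order (slice fastest).

# Sparse gather matrix for a same-padded strided 3D convolution.
# Rows are ordered kernel-element-fastest within output position so a
# gathered column reshapes to (K, npos).
conv_gather_matrix <- function(in_dims, in_ch, kernel, stride) {
  out_dims <- as.integer(ceiling(in_dims / stride))
  npos <- prod(out_dims)
  nvox <- prod(in_dims)
  K <- prod(kernel) * in_ch
  pos <- arrayInd(seq_len(npos), out_dims)           # (s,r,c) 1-based
  anchor <- sweep(pos - 1L, 2L, as.integer(stride), `*`) + 1L
  off <- as.matrix(expand.grid(ks = seq_len(kernel[1L]) - 1L -
                                 (kernel[1L] - 1L) %/% 2L,
                               kr = seq_len(kernel[2L]) - 1L -
                                 (kernel[2L] - 1L) %/% 2L,
                               kc = seq_len(kernel[3L]) - 1L -
                                 (kernel[3L] - 1L) %/% 2L))
  nk <- nrow(off)
  rows <- integer(0); cols <- integer(0)
  for (ci in seq_len(in_ch)) {
    for (k in seq_len(nk)) {
      s <- anchor[, 1L] + off[k, 1L]
      r <- anchor[, 2L] + off[k, 2L]
      cc <- anchor[, 3L] + off[k, 3L]
      ok <- s >= 1L & s <= in_dims[1L] & r >= 1L & r <= in_dims[2L] &
        cc >= 1L & cc <= in_dims[3L]
      if (!any(ok)) next
      vox <- s[ok] + (r[ok] - 1L) * in_dims[1L] +
        (cc[ok] - 1L) * in_dims[1L] * in_dims[2L]
      rows <- c(rows, (which(ok) - 1L) * K + (ci - 1L) * nk + k)
      cols <- c(cols, vox + (ci - 1L) * nvox)
    }
  }
  list(S = Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                dims = c(npos * K, nvox * in_ch)),
       out_dims = out_dims, K = K, npos = npos)
}

# Block average-pooling matrix per channel; remainder voxels fold into
# the last block.
pool_matrix <- function(in_dims, factor, n_ch) {
  out_dims <- as.integer(ceiling(in_dims / factor))
  blk <- lapply(1:3, function(a)
    pmin(out_dims[a], (seq_len(in_dims[a]) - 1L) %/% factor[a] + 1L))
  vox_in <- arrayInd(seq_len(prod(in_dims)), in_dims)
  grp <- blk[[1L]][vox_in[, 1L]] +
    (blk[[2L]][vox_in[, 2L]] - 1L) * out_dims[1L] +
    (blk[[3L]][vox_in[, 3L]] - 1L) * out_dims[1L] * out_dims[2L]
  nin <- prod(in_dims); nout <- prod(out_dims)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  counts <- tabulate(grp, nbins = nout)
  for (ci in seq_len(n_ch)) {
    rows <- c(rows, grp + (ci - 1L) * nout)
    cols <- c(cols, seq_len(nin) + (ci - 1L) * nin)
    vals <- c(vals, 1 / counts[grp])
  }
  list(P = Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                dims = c(nout * n_ch, nin * n_ch)),
       out_dims = out_dims)
}

# Nearest-neighbor upsampling matrix per channel (inverse of a block
# pooling: each output voxel copies the source block it came from).
upsample_matrix <- function(in_dims, out_dims, n_ch) {
  stride <- ceiling(out_dims / in_dims)
  src <- lapply(1:3, function(a)
    pmin(in_dims[a], (seq_len(out_dims[a]) - 1L) %/% stride[a] + 1L))
  vox_out <- arrayInd(seq_len(prod(out_dims)), out_dims)
  j <- src[[1L]][vox_out[, 1L]] +
    (src[[2L]][vox_out[, 2L]] - 1L) * in_dims[1L] +
    (src[[3L]][vox_out[, 3L]] - 1L) * in_dims[1L] * in_dims[2L]
  nin <- prod(in_dims); nout <- prod(out_dims)
  rows <- integer(0); cols <- integer(0)
  for (ci in seq_len(n_ch)) {
    rows <- c(rows, seq_len(nout) + (ci - 1L) * nout)
    cols <- c(cols, j + (ci - 1L) * nin)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(nout * n_ch, nin * n_ch))
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv_layer <- function(in_dims, in_ch, out_ch, kernel = c(3L, 3L, 3L),
                          stride = c(1L, 1L, 1L), relu = TRUE) {
  g <- conv_gather_matrix(in_dims, in_ch, kernel, stride)
  list(type = "conv", S = g$S, K = g$K, npos = g$npos,
       out_dims = g$out_dims, out_ch = out_ch, relu = relu,
       W = he_init(out_ch, g$K, g$K), b = numeric(out_ch))
}

nn_dense_layer <- function(n_in, n_out) {
  list(type = "dense", W = he_init(n_out, n_in, n_in), b = numeric(n_out))
}

nn_pool_layer <- function(in_dims, factor, n_ch) {
  p <- pool_matrix(in_dims, factor, n_ch)
  list(type = "pool", P = p$P, out_dims = p$out_dims, n_ch = n_ch)
}

nn_upsample_layer <- function(in_dims, out_dims, n_ch) {
  list(type = "upsample",
       U = upsample_matrix(in_dims, out_dims, n_ch),
       out_dims = out_dims, n_ch = n_ch)
}

conv_forward <- function(layer, X) {
  B <- ncol(X)
  M <- as.matrix(layer$S %*% X)
  dim(M) <- c(layer$K, layer$npos * B)
  Z <- layer$W %*% M + layer$b
  dim(Z) <- c(layer$out_ch, layer$npos, B)
  out <- aperm(Z, c(2L, 1L, 3L))
  dim(out) <- c(layer$npos * layer$out_ch, B)
  mask <- NULL
  if (layer$relu) {
    mask <- out > 0
    out <- out * mask
  }
  list(out = out, cache = list(M = M, mask = mask, B = B))
}

conv_backward <- function(layer, cache, dOut) {
  B <- cache$B
  if (layer$relu) dOut <- dOut * cache$mask
  dim(dOut) <- c(layer$npos, layer$out_ch, B)
  dZ <- aperm(dOut, c(2L, 1L, 3L))
  dim(dZ) <- c(layer$out_ch, layer$npos * B)
  dW <- tcrossprod(dZ, cache$M)
  db <- rowSums(dZ)
  dM <- crossprod(layer$W, dZ)
  dim(dM) <- c(layer$K * layer$npos, B)
  dX <- as.matrix(Matrix::crossprod(layer$S, dM))
  list(dX = dX, grads = list(W = dW, b = db))
}

nn_forward <- function(layers, X, train = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      f <- conv_forward(l, X)
      X <- f$out; caches[[i]] <- f$cache
    } else if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- l$W %*% X + l$b
    } else if (l$type == "pool") {
      X <- as.matrix(l$P %*% X)
    } else if (l$type == "upsample") {
      X <- as.matrix(l$U %*% X)
    } else stop("unknown layer type ", l$type)
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      b <- conv_backward(l, caches[[i]], dOut)
      dOut <- b$dX; grads[[i]] <- b$grads
    } else if (l$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(dOut, caches[[i]]$X),
                         b = rowSums(dOut))
      dOut <- crossprod(l$W, dOut)
    } else if (l$type == "pool") {
      dOut <- as.matrix(Matrix::crossprod(l$P, dOut))
    } else if (l$type == "upsample") {
      dOut <- as.matrix(Matrix::crossprod(l$U, dOut))
    }
  }
  grads
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), `-`)
  E <- exp(Z)
  sweep(E, 2L, colSums(E), `/`)
}

# Adam optimizer over the W/b arrays of all trainable layers.
adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!l$type %in% c("conv", "dense")) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(state[[i]])) next
    g <- grads[[i]]
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[i]]$W <- layers[[i]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

nn_get_weights <- function(layers) {
  lapply(layers, function(l)
    if (l$type %in% c("conv", "dense")) list(W = l$W, b = l$b) else NULL)
}

nn_set_weights <- function(layers, weights) {
  for (i in seq_along(layers)) {
    if (!is.null(weights[[i]])) {
      layers[[i]]$W <- weights[[i]]$W
      layers[[i]]$b <- weights[[i]]$b
    }
  }
  layers
}
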