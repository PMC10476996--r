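# Mixed-guideline segmentation demonstration.
#
# A small trainable segmentation learner is trained on demo-scale
# phantoms three times: on guideline-A targets, on guideline-B targets,
# and on a 50%/50% patient-level mixture. Each model is a 5-fold
# cross-validation ensemble (voxel-wise mean of fold probability maps,
# thresholded at 0.5). All three are evaluated on the same held-out
# test phantoms — the mixed model twice, once against each guideline's
# ground truth — with superior truncation before DSC / HD95 / MSD, and
# paired two-sided Wilcoxon signed-rank comparisons of coherent vs
# mixed per guideline.
#
# Learner design: the encoder is a fixed two-level mean-pooling
# pyramid (2x and 4x blocks) whose decoder is nearest-neighbor
# upsampling back to full resolution, plus vertically shifted copies
# of the 2x level that give each voxel inferior/superior context (the
# axis along which guideline B extends). The learnable part is a
# pointwise (1x1x1 convolution) fusion network over these channels
# with a sigmoid head, trained with foreground-weighted binary cross
# entropy. At this grid size the design trains in seconds on one CPU
# yet still has the ~3-voxel context needed to express the parametric
# guideline offsets.

sigmoid <- function(z) 1 / (1 + exp(-z))

# Largest 6-connected component of a binary mask (label propagation:
# each voxel takes the minimum label among its face neighbors until a
# fixed point). Empty masks pass through.
largest_component <- function(mask) {
  m <- as_mask_array(mask)
  if (sum(m) == 0L) return(m)
  d <- dim(m)
  lab <- array(seq_along(m), d) * (m != 0)
  repeat {
    nxt <- lab
    for (ax in 1:3) for (k in c(-1L, 1L)) {
      sh <- shift3d(nxt, if (ax == 1L) k else 0L,
                    if (ax == 2L) k else 0L,
                    if (ax == 3L) k else 0L)
      sh[sh == 0L] <- .Machine$integer.max
      cand <- pmin(nxt, sh)
      nxt <- ifelse(m != 0, cand, 0L)
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- table(lab[lab > 0])
  keep <- as.integer(names(ids)[which.max(ids)])
  array(as.integer(lab == keep), d)
}

#' Demo segmentation learner
#'
#' Fixed pyramid feature encoder plus a learnable pointwise fusion
#' network (see the file header for the design rationale). Because
#' every learnable layer is pointwise, the fusion network is run as a
#' dense multi-layer perceptron over a `(channels x voxels*batch)`
#' matrix, which keeps a fold's training in the low seconds on one CPU.
#'
#' @param hidden width of the two hidden pointwise layers.
#' @param shift slice offset of the vertical context channels.
#' @return a `backbone`-style list with `featurize(volume_vec, grid)`
#'   and `init(seed, bias)` functions; `n_features` channels per voxel.
#' @export
seg_backbone <- function(hidden = 12L, shift = 2L) {
  n_features <- 5L
  featurize <- function(v, grid, cache_env = NULL) {
    key <- paste(grid, collapse = "x")
    ops <- NULL
    if (!is.null(cache_env)) ops <- cache_env[[key]]
    if (is.null(ops)) {
      p2 <- pool_matrix(grid, c(2L, 2L, 2L), 1L)
      p4 <- pool_matrix(grid, c(4L, 4L, 4L), 1L)
      ops <- list(P2 = p2$P, U2 = upsample_matrix(p2$out_dims, grid, 1L),
                  P4 = p4$P, U4 = upsample_matrix(p4$out_dims, grid, 1L))
      if (!is.null(cache_env)) cache_env[[key]] <- ops
    }
    nrc <- grid[1L] * grid[2L]; ns <- grid[3L]
    shift_slices <- function(x, k) {
      m <- matrix(x, nrow = nrc)
      out <- matrix(0, nrc, ns)
      if (k >= 0L) out[, (1L + k):ns] <- m[, 1L:(ns - k)]
      else out[, 1L:(ns + k)] <- m[, (1L - k):ns]
      as.vector(out)
    }
    f2 <- as.vector(ops$U2 %*% (ops$P2 %*% v))
    f4 <- as.vector(ops$U4 %*% (ops$P4 %*% v))
    c(v, f2, f4, shift_slices(f2, shift), shift_slices(f2, -shift))
  }
  init <- function(seed, bias = 0) {
    set.seed(as.integer(seed))
    sizes <- c(n_features, hidden, hidden, 1L)
    W <- lapply(seq_len(length(sizes) - 1L), function(i)
      he_init(sizes[i + 1L], sizes[i], sizes[i]))
    b <- lapply(sizes[-1L], function(n) numeric(n))
    b[[length(b)]][] <- bias
    list(W = W, b = b)
  }
  structure(list(name = "pyramid_pointwise", featurize = featurize,
                 init = init, n_features = n_features),
            class = "backbone")
}

# MLP forward over a (channels x columns) matrix; returns logits and
# hidden activations.
seg_mlp_forward <- function(par, M) {
  A1 <- par$W[[1L]] %*% M + par$b[[1L]]
  A1 <- A1 * (A1 > 0)
  A2 <- par$W[[2L]] %*% A1 + par$b[[2L]]
  A2 <- A2 * (A2 > 0)
  Z <- par$W[[3L]] %*% A2 + par$b[[3L]]
  list(Z = Z, A1 = A1, A2 = A2)
}

# Train one segmentation fold with Adam on foreground-weighted
# voxel-wise binary cross entropy; early stop on validation loss.
# `X` is the featurized cohort: a (n_features x nvox*npatients)
# matrix; `Y` is (nvox x npatients).
train_seg_fold <- function(X, Y, train_idx, val_idx, grid, seed,
                           lr = 1e-2, batch_size = 4L, max_epochs = 40L,
                           patience = 8L, pos_weight = 4,
                           backbone = seg_backbone(), body = NULL) {
  nvox <- nrow(Y)
  # train/validate on body voxels only: the pipeline removes
  # everything outside the body before any model sees it
  cols_of <- if (is.null(body)) {
    function(ps) as.vector(vapply(ps, function(p)
      (p - 1L) * nvox + seq_len(nvox), integer(nvox)))
  } else {
    inside <- lapply(seq_len(ncol(Y)), function(p)
      (p - 1L) * nvox + which(body[, p] != 0))
    function(ps) unlist(inside[ps], use.names = FALSE)
  }
  Yv <- as.vector(Y)
  pos_frac <- mean(Yv[cols_of(train_idx)])
  par <- backbone$init(seed, bias = log(pos_frac / (1 - pos_frac)))
  adam <- lapply(rapply(par, function(x) x * 0, how = "list"),
                 identity)
  state <- list(m = adam, v = adam)
  w <- pos_weight
  best_loss <- Inf; best_par <- par; stale <- 0L; t <- 0L
  vcols <- cols_of(val_idx)
  Mval <- X[, vcols, drop = FALSE]
  yval <- Yv[vcols]
  bce <- function(p, y) {
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -mean(w * y * log(p) + (1 - y) * log(1 - p))
  }
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(train_idx)
    for (i0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[i0:min(length(ord), i0 + batch_size - 1L)]
      bcols <- cols_of(idx)
      M <- X[, bcols, drop = FALSE]
      y <- Yv[bcols]
      f <- seg_mlp_forward(par, M)
      P <- as.vector(sigmoid(f$Z))
      dZ <- matrix((P * (w * y + 1 - y) - w * y) / length(y),
                   nrow = 1L)
      dW3 <- tcrossprod(dZ, f$A2); db3 <- sum(dZ)
      dA2 <- crossprod(par$W[[3L]], dZ) * (f$A2 > 0)
      dW2 <- tcrossprod(dA2, f$A1); db2 <- rowSums(dA2)
      dA1 <- crossprod(par$W[[2L]], dA2) * (f$A1 > 0)
      dW1 <- tcrossprod(dA1, M); db1 <- rowSums(dA1)
      grads <- list(W = list(dW1, dW2, dW3), b = list(db1, db2, db3))
      t <- t + 1L
      for (li in 1:3) for (pn in c("W", "b")) {
        g <- grads[[pn]][[li]]
        state$m[[pn]][[li]] <- 0.9 * state$m[[pn]][[li]] + 0.1 * g
        state$v[[pn]][[li]] <- 0.999 * state$v[[pn]][[li]] +
          0.001 * g^2
        mh <- state$m[[pn]][[li]] / (1 - 0.9^t)
        vh <- state$v[[pn]][[li]] / (1 - 0.999^t)
        par[[pn]][[li]] <- par[[pn]][[li]] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
    pv <- as.vector(sigmoid(seg_mlp_forward(par, Mval)$Z))
    vl <- bce(pv, yval)
    if (!is.finite(vl)) stop("segmentation training diverged")
    if (vl < best_loss - 1e-9) {
      best_loss <- vl; best_par <- par; stale <- 0L
    } else stale <- stale + 1L
    if (stale >= patience) break
  }
  list(par = best_par, grid = grid)
}

# 5-fold ensemble trainer; returns list of fold models.
train_seg_kfold <- function(X, Y, patients, folds, seed, ...) {
  set.seed(as.integer(seed))
  shuffled <- sample(seq_along(patients))
  fold_of <- rep(seq_len(folds), length.out = length(shuffled))[
    order(shuffled)]
  lapply(seq_len(folds), function(f) {
    val_idx <- which(fold_of == f)
    train_idx <- setdiff(seq_along(patients), val_idx)
    train_seg_fold(X, Y, train_idx, val_idx,
                   grid = attr(X, "grid"), seed = seed + f, ...)
  })
}

# Average-ensemble prediction: voxel-wise mean of fold probability
# maps, thresholded. Returns a (nvox x npatients) binary matrix.
predict_seg_ensemble <- function(fold_models, X, nvox, threshold = 0.5) {
  P <- 0
  for (m in fold_models)
    P <- P + sigmoid(seg_mlp_forward(m$par, X)$Z)
  P <- as.vector(P) / length(fold_models)
  matrix((P >= threshold) * 1L, nrow = nvox)
}

#' Demo configuration
#'
#' @param n_train,n_test cohort sizes (training/validation vs held-out
#'   test, disjoint patients).
#' @param folds cross-validation folds.
#' @param mixture_fraction fraction of mixed-model training patients
#'   carrying guideline-B targets.
#' @param spec demo [phantom_spec()].
#' @param threshold ensemble probability threshold.
#' @param seed base seed.
#' @return a `demo_config` list.
#' @export
demo_config <- function(n_train = 15L, n_test = 8L, folds = 5L,
                        mixture_fraction = 0.5,
                        spec = phantom_spec("demo"),
                        threshold = 0.5, seed = 1L) {
  if (mixture_fraction < 0 || mixture_fraction > 1)
    stop("mixture fraction must lie in [0, 1]")
  structure(list(n_train = n_train, n_test = n_test, folds = folds,
                 mixture_fraction = mixture_fraction, spec = spec,
                 threshold = threshold, seed = as.integer(seed)),
            class = "demo_config")
}

# Feature/target matrices from a list of demo phantoms. `X` holds the
# pyramid feature channels; targets are plain full-resolution masks.
demo_matrices <- function(patients, organ_a = "Bowel_Dev",
                          organ_b = "Bowel_RTOG",
                          backbone = seg_backbone()) {
  to_rcs <- function(arr) as.vector(aperm(arr, c(2L, 3L, 1L)))
  d0 <- dim(patients[[1L]]$volume$voxels)
  grid0 <- c(d0[2L], d0[3L], d0[1L])
  cache <- new.env()
  nvox <- prod(grid0)
  X <- do.call(cbind, lapply(patients, function(p) {
    v <- zscore_normalize(p$volume)
    fv <- backbone$featurize(to_rcs(v$voxels), grid0, cache)
    t(matrix(fv, nrow = nvox))        # (n_features x nvox)
  }))
  get_mask <- function(p, nm) {
    i <- which(structure_names(p$structures) == nm)
    p$structures$structures[[i]]$mask
  }
  YA <- vapply(patients, function(p) to_rcs(get_mask(p, organ_a)),
               numeric(prod(grid0)))
  YB <- vapply(patients, function(p) to_rcs(get_mask(p, organ_b)),
               numeric(prod(grid0)))
  body <- vapply(patients, function(p) to_rcs(get_mask(p, "BODY")),
                 numeric(prod(grid0)))
  attr(X, "grid") <- grid0
  list(X = X, YA = YA, YB = YB, body = body, grid = grid0,
       dims_src = d0)
}

#' Run the mixed-guideline segmentation demonstration
#'
#' Trains the coherent-A, coherent-B and 50/50-mixed learners,
#' evaluates all three on the held-out test phantoms (the mixed model
#' once per guideline), truncates predictions superiorly before
#' geometric evaluation, and compares coherent vs mixed per guideline
#' with the two-sided Wilcoxon signed-rank test.
#'
#' @param config a [demo_config()].
#' @param out_dir optional directory for `per_case.csv`, `summary.csv`
#'   and `wilcoxon.csv`.
#' @return list with `per_case` (one row per test patient x evaluation
#'   arm), `summary` (mean +/- sd per arm) and `wilcoxon` (per
#'   guideline and metric).
#' @export
run_demo <- function(config = demo_config(), out_dir = NULL) {
  coh <- generate_cohort(config$n_train + config$n_test, config$spec,
                         base_seed = config$seed)
  train_pat <- coh$patients[seq_len(config$n_train)]
  test_pat <- coh$patients[config$n_train + seq_len(config$n_test)]
  tr <- demo_matrices(train_pat)
  te <- demo_matrices(test_pat)
  # 50/50 patient-level mixture for the mixed model
  set.seed(config$seed + 999L)
  n_b <- round(config$mixture_fraction * config$n_train)
  b_patients <- sample(config$n_train, n_b)
  Ymix <- tr$YA
  Ymix[, b_patients] <- tr$YB[, b_patients]
  models <- list(
    A = train_seg_kfold(tr$X, tr$YA, seq_len(config$n_train),
                        config$folds, config$seed + 10L, body = tr$body),
    B = train_seg_kfold(tr$X, tr$YB, seq_len(config$n_train),
                        config$folds, config$seed + 20L, body = tr$body),
    Mix = train_seg_kfold(tr$X, Ymix, seq_len(config$n_train),
                          config$folds, config$seed + 30L,
                          body = tr$body))
  arms <- list(c(model = "A", truth = "A"), c(model = "B", truth = "B"),
               c(model = "Mix", truth = "A"), c(model = "Mix", truth = "B"))
  d_src <- te$dims_src
  to_src <- function(v) aperm(array(v, c(d_src[2L], d_src[3L], d_src[1L])),
                              c(3L, 1L, 2L))
  spacing <- config$spec$spacing
  rows <- list()
  nvox <- prod(te$grid)
  for (arm in arms) {
    pred <- predict_seg_ensemble(models[[arm[["model"]]]], te$X, nvox,
                                 config$threshold)
    truth_m <- if (arm[["truth"]] == "A") te$YA else te$YB
    for (j in seq_len(config$n_test)) {
      gt <- to_src(truth_m[, j])
      # postprocess as the clinical pipeline would: nothing outside the
      # body, largest connected component only, superior truncation
      pm <- to_src(pred[, j] * te$body[, j])
      pm <- truncate_superior(largest_component(pm), gt)
      empty <- sum(pm) == 0L
      if (empty) warning("empty prediction for test patient ", j,
                         " (", arm[["model"]], " on ", arm[["truth"]],
                         ")", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        model = arm[["model"]], guideline = arm[["truth"]],
        patient = j,
        dsc = dice(pm, gt),
        hd95 = if (empty) NA_real_ else hd95(pm, gt, spacing),
        msd = if (empty) NA_real_ else msd(pm, gt, spacing))
    }
  }
  per_case <- do.call(rbind, rows)
  per_case$arm <- paste(per_case$model, "on", per_case$guideline)
  agg <- function(f) sapply(split(per_case, per_case$arm), function(d)
    sapply(d[c("dsc", "hd95", "msd")], f, na.rm = TRUE))
  mu <- agg(mean); sdv <- agg(sd)
  summary_df <- data.frame(arm = colnames(mu),
                           t(mu), t(sdv))
  names(summary_df) <- c("arm", "dsc_mean", "hd95_mean", "msd_mean",
                         "dsc_sd", "hd95_sd", "msd_sd")
  wil <- list()
  for (g in c("A", "B")) {
    coh_rows <- per_case[per_case$model == g & per_case$guideline == g, ]
    mix_rows <- per_case[per_case$model == "Mix" &
                           per_case$guideline == g, ]
    for (m in c("dsc", "hd95", "msd")) {
      ok <- stats::complete.cases(coh_rows[[m]], mix_rows[[m]])
      w <- tryCatch(
        wilcoxon_signed_rank(coh_rows[[m]][ok], mix_rows[[m]][ok]),
        error = function(e) list(statistic = NA_real_,
                                 p.value = NA_real_))
      wil[[length(wil) + 1L]] <- data.frame(
        guideline = g, metric = m,
        coherent_mean = mean(coh_rows[[m]], na.rm = TRUE),
        mixed_mean = mean(mix_rows[[m]], na.rm = TRUE),
        statistic = w$statistic, p.value = w$p.value)
    }
  }
  wilcoxon <- do.call(rbind, wil)
  out <- list(per_case = per_case, summary = summary_df,
              wilcoxon = wilcoxon)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_case, file.path(out_dir, "per_case.csv"),
              row.names = FALSE)
    write.csv(summary_df, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(wilcoxon, file.path(out_dir, "wilcoxon.csv"),
              row.names = FALSE)
  }
  out
}
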