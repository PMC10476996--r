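# Classifier training: loss weighting, custom precision monitoring,
# learning-rate scheduling, augmentation, k-fold cross validation.

#' Training configuration
#'
#' The `"bowel"` and `"pelvis"` profiles carry the clinical-scale
#' protocol: Adam with learning rate 1e-4, halved when the validation
#' loss shows no improvement for 15 epochs; early stopping when the
#' validation custom precision (CP) does not improve for 60 (bowel) or
#' 20 (pelvis) epochs; in-plane augmentation (rotation within +/-5
#' degrees and translation within +/-10 px, plus left-right flipping
#' for the bowel profile only) with per-transform probability 0.5
#' (bowel) or 0.4 (pelvis); 5-fold cross validation with an 80%/20%
#' patient-level split. `"desk"` is the reduced phantom-scale protocol
#' (learning rate 3e-3, CP patience 6, 30-epoch cap, +/-4 px
#' translation, batch 25) sized for CPU-only runs.
#'
#' @param profile `"bowel"`, `"pelvis"` or `"desk"`.
#' @param vocabulary ordered class vocabulary; must contain `"Other"`.
#' @param seed integer seed driving fold assignment, initialization,
#'   shuffling and augmentation.
#' @param ... field overrides (`lr`, `plateau_factor`,
#'   `plateau_patience`, `cp_patience`, `folds`, `batch_size`,
#'   `max_epochs`, `aug_prob`, `aug_flip`, `aug_rot_deg`,
#'   `aug_trans_px`, `backbone`, `other_class`).
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("bowel", "pelvis", "desk"),
                         vocabulary, seed = 1L, ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    bowel = list(lr = 1e-4, cp_patience = 60L, batch_size = 6L,
                 aug_prob = 0.5, aug_flip = TRUE, aug_trans_px = 10,
                 max_epochs = 1000L, plateau_patience = 15L),
    pelvis = list(lr = 1e-4, cp_patience = 20L, batch_size = 5L,
                  aug_prob = 0.4, aug_flip = FALSE, aug_trans_px = 10,
                  max_epochs = 1000L, plateau_patience = 15L),
    desk = list(lr = 3e-3, cp_patience = 6L, batch_size = 8L,
                aug_prob = 0.4, aug_flip = FALSE, aug_trans_px = 4,
                max_epochs = 30L, plateau_patience = 8L))
  cfg$profile <- profile
  cfg$plateau_factor <- 0.5
  cfg$folds <- 5L
  cfg$aug_rot_deg <- 5
  cfg$other_class <- "Other"
  cfg$backbone <- reference_backbone()
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  unknown <- setdiff(names(dots),
                     c("lr", "plateau_factor", "plateau_patience",
                       "cp_patience", "folds", "batch_size", "max_epochs",
                       "aug_prob", "aug_flip", "aug_rot_deg",
                       "aug_trans_px", "backbone", "other_class"))
  if (length(unknown)) stop("unknown train_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!cfg$other_class %in% vocabulary)
    stop("vocabulary must contain the '", cfg$other_class, "' class")
  if (cfg$folds < 2L) stop("at least 2 folds required")
  if (cfg$aug_prob < 0 || cfg$aug_prob > 1)
    stop("augmentation probability must lie in [0, 1]")
  cfg$vocabulary <- vocabulary
  class(cfg) <- "train_config"
  cfg
}

#' Balanced class weights
#'
#' Inverse label-frequency ("balanced") weights:
#' `w_c = N_total / (K * n_c)` for `K` classes. Equal counts give all
#' weights 1.
#'
#' @param label_counts named integer vector of per-class counts, all
#'   `>= 1`.
#' @return named numeric vector of weights.
#' @export
balanced_class_weights <- function(label_counts) {
  if (any(label_counts < 1))
    stop("every class needs at least one labelled sample; missing: ",
         paste(names(label_counts)[label_counts < 1], collapse = ", "))
  n <- sum(label_counts)
  k <- length(label_counts)
  n / (k * label_counts)
}

#' Weighted categorical cross entropy
#'
#' `-w_true * log(p_true)` per sample, averaged over the batch. A zero
#' probability at the true class is clamped at a small epsilon with a
#' message.
#'
#' @param probs numeric matrix (classes x batch) of probabilities, or a
#'   vector for a single sample.
#' @param true_idx integer vector of true-class row indices.
#' @param weights numeric per-class weight vector.
#' @return mean loss (scalar).
#' @export
weighted_cross_entropy <- function(probs, true_idx, weights) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1L)
  p <- probs[cbind(true_idx, seq_len(ncol(probs)))]
  if (any(p <= 0)) {
    message("clamping ", sum(p <= 0), " zero probabilities in the loss")
    p <- pmax(p, 1e-12)
  }
  mean(-weights[true_idx] * log(p))
}

#' Custom precision (CP)
#'
#' Sum of per-class precisions over every class except "Other":
#' `CP = sum_{i != j} P_i`, ranging from 0 to `n - 1` for `n` classes.
#' Classes with no predicted instances contribute precision 0.
#'
#' @param precisions named numeric vector of per-class precisions
#'   (`NA` allowed for never-predicted classes; counted as 0).
#' @param other name (or index) of the excluded "Other" class.
#' @return CP value.
#' @export
custom_precision <- function(precisions, other = "Other") {
  j <- if (is.character(other)) match(other, names(precisions)) else other
  if (is.na(j)) stop("'", other, "' not found among the precision entries")
  p <- precisions[-j]
  sum(ifelse(is.na(p), 0, p))
}

# Draw one composed in-plane affine (flip o rotation o translation)
# from the current RNG state. Returns NULL for the identity, otherwise
# an index map over the (rows x cols) plane: `idx` (clamped 1-based
# source index per target pixel) and `oob` (targets mapping outside).
draw_affine_map <- function(d_rc, config) {
  flip <- isTRUE(config$aug_flip) && runif(1) < config$aug_prob
  rot <- runif(1) < config$aug_prob
  theta <- if (rot) runif(1, -config$aug_rot_deg, config$aug_rot_deg) *
    pi / 180 else 0
  trans <- runif(1) < config$aug_prob
  tr <- if (trans) runif(2, -config$aug_trans_px, config$aug_trans_px)
        else c(0, 0)
  if (!flip && theta == 0 && all(tr == 0)) return(NULL)
  ctr <- (d_rc + 1) / 2
  tgt <- as.matrix(expand.grid(r = seq_len(d_rc[1L]),
                               c = seq_len(d_rc[2L])))
  # inverse map: undo translation, rotation, then flip (columns)
  p <- sweep(tgt, 2L, ctr)
  p <- sweep(p, 2L, tr)
  if (theta != 0) {
    cs <- cos(-theta); sn <- sin(-theta)
    p <- cbind(p[, 1L] * cs - p[, 2L] * sn,
               p[, 1L] * sn + p[, 2L] * cs)
  }
  if (flip) p[, 2L] <- -p[, 2L]
  src <- round(sweep(p, 2L, ctr, `+`))
  ok <- src[, 1L] >= 1 & src[, 1L] <= d_rc[1L] &
    src[, 2L] >= 1 & src[, 2L] <= d_rc[2L]
  idx <- ifelse(ok, src[, 1L] + (src[, 2L] - 1L) * d_rc[1L], 1L)
  list(idx = idx, oob = !ok)
}

# Apply an affine index map to one feature column: a vector in
# (row, col, slice-and-channel) layout viewed as (rows*cols x rest).
apply_affine_map <- function(v, map, nrc) {
  m <- matrix(v, nrow = nrc)
  m <- m[map$idx, , drop = FALSE]
  if (any(map$oob)) m[map$oob, ] <- 0
  as.vector(m)
}

#' In-plane augmentation of a classifier sample
#'
#' Left-right flip, rotation and translation, each applied
#' independently with the profile probability, as one composed 2D
#' affine map per draw, identically to both channels, with
#' nearest-neighbor resampling (so AddMap values stay in
#' `{0, 0.5, 1}`). Uses the current RNG state.
#'
#' @param sample a [classifier_sample()].
#' @param config a [train_config()] (fields `aug_prob`, `aug_flip`,
#'   `aug_rot_deg`, `aug_trans_px`).
#' @return augmented [classifier_sample()].
#' @export
augment <- function(sample, config) {
  d <- dim(sample$ct)              # (s, r, c)
  map <- draw_affine_map(d[2:3], config)
  if (is.null(map)) return(sample)
  nrc <- d[2L] * d[3L]
  remap <- function(arr) {
    v <- as.vector(aperm(arr, c(2L, 3L, 1L)))   # (r, c, s)
    out <- apply_affine_map(v, map, nrc)
    aperm(array(out, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  }
  out <- sample
  out$ct <- remap(sample$ct)
  out$addmap <- remap(sample$addmap)
  out
}

# ---- reference backbone ----------------------------------------------

#' Desk-scale reference classifier backbone
#'
#' A compact 3D CNN: block average-pooling of the two-channel input,
#' two same-padded 3x3x3 convolutions (ReLU; the second with stride 2),
#' and a softmax head over the flattened coarse feature map. The
#' flatten (rather than global average pooling) keeps coarse spatial
#' position, which is what separates left from right femoral heads.
#' Any list with the same `build`/`forward`/`backward`/`step` contract
#' can be dropped in as a heavier backbone.
#'
#' @param pool pooling factor `(slice, row, col)` applied to the input.
#' @param channels widths of the two convolution blocks.
#' @return a `backbone` list.
#' @export
reference_backbone <- function(pool = c(4L, 4L, 2L), channels = c(8L, 16L)) {
  build <- function(input_grid, n_classes) {
    # input_grid is the preprocess target grid (rows, cols, slices);
    # feature vectors use the same (row, col, slice) order
    in_dims <- as.integer(input_grid)
    pl <- nn_pool_layer(in_dims, pool, 2L)
    c1 <- nn_conv_layer(pl$out_dims, 2L, channels[1L])
    c2 <- nn_conv_layer(c1$out_dims, channels[1L], channels[2L],
                        stride = c(2L, 2L, 2L))
    head <- nn_dense_layer(prod(c2$out_dims) * channels[2L], n_classes)
    list(layers = list(pl, c1, c2, head), input_grid = input_grid,
         n_classes = n_classes)
  }
  structure(list(name = "compact_cnn", build = build), class = "backbone")
}

# Samples -> dense batch matrix. Feature vectors are channel-major
# with voxels in (row, col, slice) order, so the in-plane plane is
# contiguous and augmentation is a single row gather.
samples_to_matrix <- function(samples) {
  vapply(samples, function(s)
    c(as.vector(aperm(s$ct, c(2L, 3L, 1L))),
      as.vector(aperm(s$addmap, c(2L, 3L, 1L)))),
    numeric(2L * length(samples[[1L]]$ct)))
}

model_probs <- function(model, X) {
  softmax_cols(nn_forward(model$layers, X, train = FALSE)$out)
}

# ---- fold training ----------------------------------------------------

#' Train one cross-validation fold
#'
#' Minibatch Adam on weighted categorical cross entropy with on-the-fly
#' augmentation; per-epoch validation loss, per-class precision, CP and
#' accuracy are logged. The learning rate is halved when the validation
#' loss shows no improvement for `plateau_patience` epochs; training
#' stops when the validation CP has not improved for `cp_patience`
#' epochs (or at `max_epochs`), and the weights of the epoch with the
#' highest validation CP are returned.
#'
#' @param samples list of labelled [classifier_sample()]s.
#' @param train_idx,val_idx disjoint index vectors into `samples`
#'   (split at patient level by [train_kfold()]).
#' @param config a [train_config()].
#' @param seed fold seed.
#' @return a `fold_model`: `model`, `vocabulary`, `log` (data frame),
#'   `best_epoch`, `best_cp`, `class_weights`.
#' @export
train_fold <- function(samples, train_idx, val_idx, config, seed = 1L) {
  set.seed(as.integer(seed))
  voc <- config$vocabulary
  labels <- vapply(samples, function(s) s$label, character(1))
  if (anyNA(labels[c(train_idx, val_idx)]))
    stop("all training/validation samples need labels")
  y <- match(labels, voc)
  if (anyNA(y[c(train_idx, val_idx)])) stop("label outside vocabulary")
  counts <- table(factor(labels[train_idx], levels = voc))
  weights <- balanced_class_weights(as.integer(counts) |>
                                      setNames(voc))
  grid <- dim(samples[[train_idx[1L]]]$ct)
  input_grid <- c(grid[2L], grid[3L], grid[1L])    # (rows, cols, slices)
  nrc <- grid[2L] * grid[3L]
  model <- config$backbone$build(input_grid, length(voc))
  state <- adam_init(model$layers)
  lr <- config$lr
  Xall <- samples_to_matrix(samples)
  Xval <- Xall[, val_idx, drop = FALSE]
  yval <- y[val_idx]
  best_cp <- -Inf; best_weights <- NULL; best_epoch <- 0L
  best_val_loss <- Inf; loss_stale <- 0L; cp_stale <- 0L
  t <- 0L
  log <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    train_loss <- 0; nb <- 0L
    for (i0 in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[i0:min(length(ord), i0 + config$batch_size - 1L)]
      X <- Xall[, idx, drop = FALSE]
      for (j in seq_along(idx)) {      # on-the-fly augmentation
        map <- draw_affine_map(grid[2:3], config)
        if (!is.null(map)) X[, j] <- apply_affine_map(X[, j], map, nrc)
      }
      f <- nn_forward(model$layers, X)
      P <- softmax_cols(f$out)
      yb <- y[idx]
      train_loss <- train_loss + weighted_cross_entropy(P, yb, weights)
      nb <- nb + 1L
      Y <- matrix(0, length(voc), length(idx))
      Y[cbind(yb, seq_along(idx))] <- 1
      dlogits <- sweep(P - Y, 2L, weights[yb], `*`) / length(idx)
      grads <- nn_backward(model$layers, f$caches, dlogits)
      t <- t + 1L
      upd <- adam_step(model$layers, grads, state, lr, t)
      model$layers <- upd$layers; state <- upd$state
    }
    train_loss <- train_loss / nb
    if (!is.finite(train_loss))
      stop("non-finite training loss at epoch ", epoch, "; aborting fold")
    Pv <- model_probs(model, Xval)
    val_loss <- weighted_cross_entropy(Pv, yval, weights)
    pred <- apply(Pv, 2L, which.max)
    prec <- vapply(seq_along(voc), function(k) {
      npred <- sum(pred == k)
      if (npred == 0L) NA_real_ else sum(pred == k & yval == k) / npred
    }, numeric(1))
    names(prec) <- voc
    cp <- custom_precision(prec, config$other_class)
    acc <- mean(pred == yval)
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                               train_loss = train_loss,
                               val_loss = val_loss, val_cp = cp,
                               val_accuracy = acc)
    if (cp > best_cp + 1e-12) {
      best_cp <- cp; best_epoch <- epoch
      best_weights <- nn_get_weights(model$layers)
      cp_stale <- 0L
    } else cp_stale <- cp_stale + 1L
    if (val_loss < best_val_loss - 1e-12) {
      best_val_loss <- val_loss; loss_stale <- 0L
    } else loss_stale <- loss_stale + 1L
    if (loss_stale >= config$plateau_patience) {
      lr <- lr * config$plateau_factor
      loss_stale <- 0L
    }
    if (cp_stale >= config$cp_patience) break
  }
  model$layers <- nn_set_weights(model$layers, best_weights)
  structure(list(model = model, vocabulary = voc,
                 log = do.call(rbind, log), best_epoch = best_epoch,
                 best_cp = best_cp, class_weights = weights),
            class = "fold_model")
}

#' Train a k-fold cross-validation ensemble
#'
#' Patients are shuffled and partitioned into `folds` groups, so each
#' patient appears in exactly one fold's validation set and sibling
#' structures never straddle a split. Per-fold class weights are
#' computed on that fold's training labels; a class absent from any
#' fold's training set is a fatal error.
#'
#' @param samples list of labelled [classifier_sample()]s with
#'   `patient_id`s.
#' @param config a [train_config()].
#' @return an `ensemble_model`: `folds` (list of fold models), shared
#'   `vocabulary`, `input_grid` fingerprint, `fold_patients`.
#' @export
train_kfold <- function(samples, config) {
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  patients <- unique(pids)
  if (length(patients) < config$folds)
    stop("need at least as many patients as folds")
  set.seed(config$seed)
  shuffled <- sample(patients)
  fold_of <- setNames(rep(seq_len(config$folds), length.out =
                            length(shuffled)), shuffled)
  labels <- vapply(samples, function(s) s$label, character(1))
  folds <- vector("list", config$folds)
  fold_patients <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    val_idx <- which(fold_of[pids] == f)
    train_idx <- setdiff(seq_along(samples), val_idx)
    missing <- setdiff(config$vocabulary, labels[train_idx])
    if (length(missing))
      stop("class(es) ", paste(missing, collapse = ", "),
           " absent from fold ", f, " training data; enlarge the cohort")
    folds[[f]] <- train_fold(samples, train_idx, val_idx, config,
                             seed = config$seed + f)
    folds[[f]]$fold <- f
    fold_patients[[f]] <- names(fold_of)[fold_of == f]
  }
  grid <- dim(samples[[1L]]$ct)
  structure(list(folds = folds, vocabulary = config$vocabulary,
                 input_grid = c(grid[2L], grid[3L], grid[1L]),
                 fold_patients = fold_patients),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d folds, %d classes, input %s\n",
              length(x$folds), length(x$vocabulary),
              paste(x$input_grid, collapse = "x")))
  for (f in x$folds)
    cat(sprintf("  fold %d: best epoch %d, val CP %.3f\n",
                f$fold, f$best_epoch, f$best_cp))
  invisible(x)
}
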