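# Training protocol: class weights, weighted loss, custom precision,
# augmentation, fold training.

test_that("balanced class weights follow N / (K * n_c)", {
  expect_equal(balanced_class_weights(c(A = 10, B = 30)),
               c(A = 2, B = 2 / 3), tolerance = 1e-12)
  expect_equal(unname(balanced_class_weights(c(A = 5, B = 5, C = 5))),
               c(1, 1, 1))
  expect_equal(balanced_class_weights(c(A = 1, B = 1, C = 2)),
               c(A = 4 / 3, B = 4 / 3, C = 2 / 3), tolerance = 1e-12)
  expect_error(balanced_class_weights(c(A = 3, B = 0)), "B")
})

test_that("weighted cross entropy matches closed forms", {
  expect_equal(weighted_cross_entropy(c(1, 0), 1L, c(1, 1)), 0)
  expect_equal(weighted_cross_entropy(c(0.5, 0.5), 1L, c(1, 1)), log(2),
               tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(c(0.5, 0.5), 1L, c(2, 1)),
               2 * log(2), tolerance = 1e-12)   # linear in the weight
  # batch mean over a matrix
  P <- cbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(weighted_cross_entropy(P, c(1L, 2L), c(1, 1)),
               mean(c(log(2), -log(0.75))), tolerance = 1e-12)
  expect_message(z <- weighted_cross_entropy(c(0, 1), 1L, c(1, 1)),
                 "clamping")
  expect_true(is.finite(z))
})

test_that("custom precision sums non-Other precisions with NA -> 0", {
  expect_equal(custom_precision(c(A = 1.0, B = 0.9, Other = 0.5)), 1.9)
  expect_equal(custom_precision(c(A = 1, B = 1, C = 1, Other = 0.2)), 3)
  expect_equal(custom_precision(c(A = 0, B = 0, Other = 1)), 0)
  expect_equal(custom_precision(c(A = NA, B = 0.5, Other = 1)), 0.5)
  expect_error(custom_precision(c(A = 1, B = 1)), "Other")
  # monotone under converting non-Other false positives to Other
  set.seed(77)
  voc <- c("A", "B", "C", "Other")
  for (rep in 1:20) {
    truth <- sample(voc, 60, replace = TRUE)
    pred <- sample(voc, 60, replace = TRUE)
    cp_of <- function(pr) {
      r <- classification_report(truth, pr, voc)
      p <- r$per_class$precision
      p[r$per_class$precision_undefined] <- 0
      names(p) <- voc
      custom_precision(p)
    }
    fp <- which(pred != truth & pred != "Other")
    if (length(fp) == 0) next
    pred2 <- pred
    pred2[sample(fp, ceiling(length(fp) / 2))] <- "Other"
    expect_gte(cp_of(pred2), cp_of(pred) - 1e-12)
  }
})

test_that("augmentation preserves the AddMap codomain, label and shape", {
  smp <- tiny_samples(1)[[1]]
  cfg <- train_config("desk", vocabulary = c("A", "B", "Other"),
                      aug_prob = 1, aug_flip = FALSE)
  set.seed(5)
  for (i in 1:10) {
    out <- augment(smp, cfg)
    expect_true(all(out$addmap %in% c(0, 0.5, 1)))
    expect_identical(dim(out$ct), dim(smp$ct))
    expect_identical(out$label, smp$label)
  }
  # probability 0 -> identity
  cfg0 <- train_config("desk", vocabulary = c("A", "B", "Other"),
                       aug_prob = 0)
  expect_identical(augment(smp, cfg0), smp)
  # two flips compose to the identity
  cfg_flip <- train_config("desk", vocabulary = c("A", "B", "Other"),
                           aug_prob = 1, aug_flip = TRUE,
                           aug_rot_deg = 0, aug_trans_px = 0)
  once <- augment(smp, cfg_flip)
  twice <- augment(once, cfg_flip)
  expect_false(identical(once$addmap, smp$addmap))
  expect_identical(twice$addmap, smp$addmap)
  expect_identical(twice$ct, smp$ct)
})

test_that("fast augmentation path equals the sample-level operation", {
  smp <- tiny_samples(1)[[1]]
  cfg <- train_config("desk", vocabulary = c("A", "B", "Other"),
                      aug_prob = 1, aug_flip = TRUE)
  d <- dim(smp$ct)
  set.seed(12)
  ref <- augment(smp, cfg)
  set.seed(12)
  map <- oarclass:::draw_affine_map(d[2:3], cfg)
  v <- oarclass:::samples_to_matrix(list(smp))[, 1]
  fast <- oarclass:::apply_affine_map(v, map, d[2] * d[3])
  expect_equal(fast, oarclass:::samples_to_matrix(list(ref))[, 1])
})

test_that("train_fold reaches maximal CP on a separable toy set and stops early", {
  voc <- c("A", "B", "Other")
  samples <- tiny_samples(6, vocabulary = voc, seed = 2)
  cfg <- train_config("desk", vocabulary = voc, seed = 1,
                      batch_size = 4L, max_epochs = 60L, lr = 1e-2,
                      cp_patience = 8L, aug_prob = 0,
                      backbone = reference_backbone(pool = c(2L, 2L, 2L),
                                                    channels = c(4L, 8L)))
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  val_idx <- which(pids %in% c("p01", "p02", "p07", "p08", "p13", "p14"))
  train_idx <- setdiff(seq_along(samples), val_idx)
  fm <- train_fold(samples, train_idx, val_idx, cfg, seed = 3)
  expect_equal(fm$best_cp, length(voc) - 1)   # separable -> n - 1
  # early stop: exactly cp_patience epochs after the best epoch
  expect_identical(nrow(fm$log), fm$best_epoch + cfg$cp_patience)
  # deterministic under the same seed
  fm2 <- train_fold(samples, train_idx, val_idx, cfg, seed = 3)
  expect_identical(fm$log, fm2$log)
  expect_identical(fm$best_epoch, fm2$best_epoch)
})

test_that("train_kfold partitions patients and computes per-fold weights", {
  voc <- c("A", "B", "Other")
  samples <- tiny_samples(5, vocabulary = voc, seed = 4)
  cfg <- train_config("desk", vocabulary = voc, seed = 9,
                      folds = 5L, batch_size = 5L, max_epochs = 1L,
                      backbone = reference_backbone(pool = c(2L, 2L, 2L),
                                                    channels = c(2L, 4L)))
  ens <- train_kfold(samples, cfg)
  expect_length(ens$folds, 5)
  all_val <- unlist(ens$fold_patients)
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  expect_setequal(all_val, unique(pids))      # union = full cohort
  expect_identical(anyDuplicated(all_val), 0L)  # each patient once
  # class absent from a fold's training set is fatal
  bad <- samples[1:6]                          # class A only spans p01-p04
  cfg_bad <- train_config("desk", vocabulary = voc, seed = 1,
                          folds = 3L, max_epochs = 1L)
  expect_error(train_kfold(bad, cfg_bad), "absent from fold")
})

test_that("training profiles carry the published protocol values", {
  voc <- c("X", "Other")
  bowel <- train_config("bowel", vocabulary = voc)
  pelvis <- train_config("pelvis", vocabulary = voc)
  expect_equal(bowel$lr, 1e-4)
  expect_equal(bowel$plateau_factor, 0.5)
  expect_equal(bowel$plateau_patience, 15L)
  expect_equal(bowel$cp_patience, 60L)
  expect_equal(pelvis$cp_patience, 20L)
  expect_equal(bowel$aug_prob, 0.5)
  expect_equal(pelvis$aug_prob, 0.4)
  expect_true(bowel$aug_flip)
  expect_false(pelvis$aug_flip)
  expect_equal(bowel$aug_rot_deg, 5)
  expect_equal(bowel$aug_trans_px, 10)
  expect_equal(bowel$folds, 5L)
  expect_error(train_config("bowel", vocabulary = c("X", "Y")), "Other")
})
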