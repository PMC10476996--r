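# Ensemble inference: keyword lists, voting, name exclusion, batch
# classification.

test_that("exclusion keyword lists match the published profiles", {
  bowel <- exclusion_keywords("bowel")
  pelvis <- exclusion_keywords("pelvis")
  expect_identical(bowel,
    c("tuning", "help", "x_", "y_", "opt_", "dose", "match",
      "artefakter", "artifakter", "artefakt", "gtv", "ctv", "ptv",
      "ring", "bowelbag", "abdomen", "tarm", "buk", "peritoneum"))
  expect_identical(pelvis,
    c("tuning", "help", "x_", "y_", "z_", "opt", "dose", "match",
      "artefakter", "artifakter", "artefakt", "gtv", "ctv", "ptv",
      "ring", "analcanal"))
  expect_identical(tolower(bowel), bowel)
  expect_identical(tolower(pelvis), pelvis)
})

test_that("majority vote uses votes, then summed probability, then order", {
  voc <- c("A", "B", "C")
  pm <- function(...) {
    m <- cbind(...)
    rownames(m) <- voc
    m
  }
  flat <- pm(c(1, 0, 0) / 1, c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 1, 0))
  expect_identical(majority_vote(c("A", "A", "A", "B", "B"), flat, voc),
                   "A")
  # 2-2-1 tie broken by summed probability
  probs <- pm(c(0.9, 0.1, 0), c(0.8, 0.2, 0), c(0.05, 0.9, 0.05),
              c(0.05, 0.9, 0.05), c(0.3, 0.3, 0.4))
  expect_identical(majority_vote(c("A", "A", "B", "B", "C"), probs, voc),
                   "B")  # summed: A 2.1, B 2.4
  probs2 <- pm(c(0.99, 0.01, 0), c(0.99, 0.01, 0), c(0.1, 0.85, 0.05),
               c(0.1, 0.85, 0.05), c(0.3, 0.3, 0.4))
  expect_identical(majority_vote(c("A", "A", "B", "B", "C"), probs2,
                                 voc), "A")  # summed: A 2.48, B 2.02
  # exact probability tie -> vocabulary order
  even <- pm(c(1, 0, 0), c(0, 1, 0))
  expect_identical(majority_vote(c("B", "A"), even, voc), "A")
  expect_identical(majority_vote("C", pm(c(0, 0, 1)), voc), "C")
})

test_that("name exclusion forces Other on lowercase substring hits", {
  pelvis <- exclusion_keywords("pelvis")
  bowel <- exclusion_keywords("bowel")
  expect_identical(name_exclusion("Bladder", "PTV_boost", pelvis),
                   "Other")
  expect_identical(name_exclusion("Bladder", "Bladder", pelvis),
                   "Bladder")
  expect_identical(name_exclusion("Bowel_RTOG", "Opt_bowel",
                                  bowel), "Other")
  expect_identical(name_exclusion("Rectum", "HELP struct", pelvis),
                   "Other")          # lowercase comparison
  expect_identical(name_exclusion("Rectum", "Rektum", pelvis), "Rectum")
})

# Deterministic random-weight ensemble on the desk grid (no training
# needed to exercise the inference plumbing).
fake_ensemble <- function(voc, input_grid = c(40L, 44L, 24L),
                          folds = 5L, seed = 1L) {
  set.seed(seed)
  backbone <- reference_backbone()
  fold_models <- lapply(seq_len(folds), function(f)
    list(model = backbone$build(input_grid, length(voc)), fold = f))
  structure(list(folds = fold_models, vocabulary = voc,
                 input_grid = input_grid,
                 fold_patients = list()),
            class = "ensemble_model")
}

test_that("predict_folds yields one probability vector per fold", {
  voc <- phantom_vocabulary()
  ens <- fake_ensemble(voc)
  p <- generate_phantom(phantom_spec("desk"), 21, "p")
  smp <- suppressMessages(preprocess_patient(
    p$volume, p$structures, preprocess_config("desk")))[[1]]
  pf <- predict_folds(ens, smp)
  expect_length(pf$labels, 5)
  expect_identical(dim(pf$probs), c(length(voc), 5L))
  expect_equal(unname(colSums(pf$probs)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pf$probs >= 0))
  # identical fold weights -> identical labels
  ens_same <- ens
  for (i in 2:5) ens_same$folds[[i]] <- ens_same$folds[[1]]
  pf_same <- predict_folds(ens_same, smp)
  expect_length(unique(pf_same$labels), 1)
  # grid mismatch is fatal
  bad <- smp
  bad$ct <- bad$ct[, 1:10, ]; bad$addmap <- bad$addmap[, 1:10, ]
  expect_error(predict_folds(ens, bad), "grid")
})

test_that("classify_patients reports every eligible structure and sorts copies", {
  dir <- withr::local_tempdir()
  generate_cohort(2, phantom_spec("desk"), base_seed = 31, dir = dir)
  voc <- phantom_vocabulary()
  ens <- fake_ensemble(voc, seed = 2)
  cfg <- preprocess_config("desk")
  pd <- file.path(dir, c("patient001", "patient002"))
  out1 <- withr::local_tempdir()
  rep_on <- classify_patients(ens, pd, cfg, exclusion = TRUE,
                              out_dir = out1)
  n_structs <- sum(vapply(pd, function(d)
    length(list.files(d, pattern = "^mask_")) - 1L, integer(1)))
  expect_identical(nrow(rep_on), n_structs)       # body not classified
  expect_true(all(rep_on$final_label %in% voc))
  # rerun determinism
  rep_again <- classify_patients(ens, pd, cfg, exclusion = TRUE)
  expect_identical(rep_on[names(rep_again)], rep_again)
  # exclusion only maps toward Other
  rep_off <- classify_patients(ens, pd, cfg, exclusion = FALSE)
  expect_gte(sum(rep_on$final_label == "Other"),
             sum(rep_off$final_label == "Other"))
  changed <- rep_on$final_label != rep_off$final_label
  expect_true(all(rep_on$final_label[changed] == "Other"))
  # nuisance names got excluded
  nuisance <- grepl("ptv|ring|opt|ctv", tolower(rep_on$structure))
  expect_true(all(rep_on$final_label[nuisance] == "Other"))
  # sorted copy tree under the final labels
  expect_true(file.exists(file.path(out1, "predictions.csv")))
  for (i in seq_len(nrow(rep_on))) {
    expect_true(file.exists(file.path(
      out1, rep_on$final_label[i], rep_on$patient_id[i],
      paste0("mask_", rep_on$structure[i], ".nii.gz"))))
  }
})

test_that("ensembles round-trip through save/load", {
  voc <- c("A", "Other")
  ens <- fake_ensemble(voc, input_grid = c(8L, 8L, 6L), folds = 2L)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_identical(back$vocabulary, voc)
  expect_identical(back$input_grid, ens$input_grid)
  expect_equal(back$folds[[1]]$model$layers[[2]]$W,
               ens$folds[[1]]$model$layers[[2]]$W)
})
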