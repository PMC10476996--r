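# Ensemble inference: per-fold prediction, majority voting, structure-
# name exclusion, sorted copies and report.

#' Structure-name exclusion keyword lists
#'
#' Profile-specific lowercase keyword fragments. After majority voting,
#' a structure whose stored name contains any keyword as a substring
#' (lowercase comparison) is forced to the class `"Other"`.
#'
#' @param profile `"bowel"`, `"pelvis"` or `"desk"` (the desk phantom
#'   profile reuses the pelvis list).
#' @return character vector of lowercase keywords.
#' @export
exclusion_keywords <- function(profile = c("bowel", "pelvis", "desk")) {
  profile <- match.arg(profile)
  bowel <- c("tuning", "help", "x_", "y_", "opt_", "dose", "match",
             "artefakter", "artifakter", "artefakt", "gtv", "ctv", "ptv",
             "ring", "bowelbag", "abdomen", "tarm", "buk", "peritoneum")
  pelvis <- c("tuning", "help", "x_", "y_", "z_", "opt", "dose", "match",
              "artefakter", "artifakter", "artefakt", "gtv", "ctv", "ptv",
              "ring", "analcanal")
  switch(profile, bowel = bowel, pelvis = pelvis, desk = pelvis)
}

#' Per-fold prediction for one sample
#'
#' @param ensemble an `ensemble_model` from [train_kfold()].
#' @param sample a [classifier_sample()] on the ensemble's input grid.
#' @return list with `labels` (character per fold) and `probs`
#'   (classes x folds matrix; columns sum to 1).
#' @export
predict_folds <- function(ensemble, sample) {
  grid <- dim(sample$ct)
  if (!identical(as.integer(c(grid[2L], grid[3L], grid[1L])),
                 as.integer(ensemble$input_grid)))
    stop("sample grid does not match the ensemble input grid")
  X <- samples_to_matrix(list(sample))
  probs <- vapply(ensemble$folds,
                  function(f) as.vector(model_probs(f$model, X)),
                  numeric(length(ensemble$vocabulary)))
  rownames(probs) <- ensemble$vocabulary
  labels <- ensemble$vocabulary[apply(probs, 2L, which.max)]
  list(labels = labels, probs = probs)
}

#' Majority vote over fold predictions
#'
#' The label with the most votes wins; ties are broken by the highest
#' summed probability across folds for the tied labels, remaining ties
#' by vocabulary order.
#'
#' @param labels character vector of per-fold argmax labels.
#' @param probs classes x folds probability matrix (rownames =
#'   vocabulary), used for tie-breaking.
#' @param vocabulary ordered class vocabulary.
#' @return the voted label.
#' @export
majority_vote <- function(labels, probs, vocabulary) {
  if (length(labels) == 0L) stop("no fold predictions to vote over")
  votes <- table(factor(labels, levels = vocabulary))
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  sums <- rowSums(probs)[top]
  top <- top[sums == max(sums)]
  top[order(match(top, vocabulary))][1L]
}

#' Structure-name exclusion
#'
#' If the lowercased structure name contains any keyword as a
#' substring, the final label is `"Other"`; otherwise the voted label
#' stands. Applied after voting.
#'
#' @param voted_label label from [majority_vote()].
#' @param structure_name stored structure name.
#' @param keywords lowercase keyword vector
#'   (see [exclusion_keywords()]).
#' @param other_class name of the catch-all class.
#' @return the final label.
#' @export
name_exclusion <- function(voted_label, structure_name, keywords,
                           other_class = "Other") {
  nm <- tolower(structure_name)
  hit <- any(vapply(keywords, function(k) grepl(k, nm, fixed = TRUE),
                    logical(1)))
  if (hit) other_class else voted_label
}

#' Classify every structure of a patient cohort
#'
#' Loads each patient folder, preprocesses every structure (with
#' in-plane downscaling enabled, as at inference), classifies it with
#' each fold model, applies majority voting and (optionally)
#' structure-name exclusion, writes a delimited report and sorts
#' copies of the structure files into per-class output folders.
#' Per-structure failures are logged and never abort the batch.
#'
#' @param ensemble an `ensemble_model`.
#' @param patient_dirs character vector of patient folders.
#' @param preprocess_cfg a [preprocess_config()].
#' @param exclusion `TRUE` to apply structure-name exclusion.
#' @param keywords keyword list; defaults to the preprocess profile's
#'   list.
#' @param out_dir optional output root for the report
#'   (`predictions.csv`) and the class-sorted copy tree.
#' @param format patient folder format, `"nifti"` or `"dicom"`.
#' @return data frame with one row per eligible structure: patient id,
#'   structure name, per-fold labels, voted label, final label,
#'   exclusion flag and per-class mean probabilities.
#' @export
classify_patients <- function(ensemble, patient_dirs, preprocess_cfg,
                              exclusion = TRUE, keywords = NULL,
                              out_dir = NULL, format = "nifti") {
  if (is.null(keywords))
    keywords <- exclusion_keywords(preprocess_cfg$profile)
  cfg <- preprocess_cfg
  cfg$allow_downscale <- TRUE
  voc <- ensemble$vocabulary
  rows <- list()
  for (pd in patient_dirs) {
    rec <- tryCatch({
      pat <- load_patient(pd, format = format)
      if (is.na(pat$structures$body_index))
        stop("no body structure for ", basename(pd))
      preprocess_patient(pat$volume, pat$structures, cfg)
    }, error = function(e) {
      warning("patient ", basename(pd), " failed: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(rec)) next
    for (smp in rec) {
      pf <- predict_folds(ensemble, smp)
      voted <- majority_vote(pf$labels, pf$probs, voc)
      final <- if (exclusion)
        name_exclusion(voted, smp$name, keywords) else voted
      row <- data.frame(patient_id = smp$patient_id,
                        structure = smp$name,
                        voted_label = voted, final_label = final,
                        exclusion_fired = final != voted,
                        stringsAsFactors = FALSE)
      for (f in seq_along(pf$labels))
        row[[paste0("fold", f)]] <- pf$labels[f]
      mp <- rowMeans(pf$probs)
      for (cl in voc) row[[paste0("p_", cl)]] <- mp[[cl]]
      row$source_file <- attr(smp, "source_file") %||% NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), structure = character(0),
               voted_label = character(0), final_label = character(0),
               exclusion_fired = logical(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    for (i in seq_len(nrow(report))) {
      src <- report$source_file[i]
      if (is.na(src)) next
      write_structure_copy(src, report$final_label[i],
                           report$patient_id[i], out_dir,
                           vocabulary = voc)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
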