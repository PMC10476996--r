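# Patient-level reading and writing.
#
# A NIfTI patient folder holds `image.nii.gz` (the CT, in HU) plus one
# `mask_<StructureName>.nii.gz` per structure — the layout produced by
# the usual DICOM-to-NIfTI structure converters, and by
# write_patient_nifti(). A DICOM patient folder holds `CT_*.dcm` slices
# and one RT-STRUCT (`RS*.dcm`).

#' Load one patient's CT and structure set
#'
#' Reads the CT in Hounsfield units and every non-empty structure as a
#' binary mask on the CT grid. Empty structures are dropped with a
#' warning; unreadable structure files are skipped with a warning and
#' never abort the patient. The body structure, when present by name,
#' is designated via [find_body()] (missing body is not an error at
#' load time; preprocessing requires it).
#'
#' @param path patient directory.
#' @param format `"nifti"` or `"dicom"`.
#' @return list with `volume` ([image_volume()]) and
#'   `structures` ([structure_set()]).
#' @export
load_patient <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("patient directory not found: ", path)
  pid <- basename(normalizePath(path, mustWork = FALSE))
  if (format == "nifti") {
    ct_file <- c(file.path(path, "image.nii.gz"), file.path(path, "image.nii"),
                 file.path(path, "ct.nii.gz"), file.path(path, "ct.nii"))
    ct_file <- ct_file[file.exists(ct_file)][1L]
    if (is.na(ct_file)) stop("no CT volume (image.nii[.gz]) in ", path)
    ct <- read_nifti(ct_file)
    vol <- image_volume(ct$data, ct$spacing, ct$origin)
    mask_files <- sort(list.files(path, pattern = "^mask_.*\\.nii(\\.gz)?$",
                                  full.names = TRUE))
    structures <- list()
    for (f in mask_files) {
      nm <- sub("^mask_", "", sub("\\.nii(\\.gz)?$", "", basename(f)))
      m <- tryCatch(read_nifti(f), error = function(e) {
        warning("skipping unreadable structure file ", basename(f), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(m)) next
      if (!identical(dim(m$data), dim(vol$voxels))) {
        warning("skipping structure '", nm, "': grid differs from CT",
                call. = FALSE)
        next
      }
      if (all(m$data == 0)) {
        warning("dropping empty structure '", nm, "'", call. = FALSE)
        next
      }
      structures[[length(structures) + 1L]] <-
        named_structure(nm, array(as.integer(m$data != 0), dim(m$data)))
      attr(structures[[length(structures)]], "source_file") <- f
    }
  } else {
    ct_files <- sort(list.files(path, pattern = "^CT_.*\\.dcm$",
                                full.names = TRUE))
    if (length(ct_files) == 0L) stop("no DICOM CT slices (CT_*.dcm) in ", path)
    vol <- dcm_read_ct_series(ct_files)
    rs_files <- list.files(path, pattern = "^RS.*\\.dcm$", full.names = TRUE)
    structures <- list()
    if (length(rs_files)) {
      raw_structs <- tryCatch(dcm_read_rtstruct(rs_files[[1L]], vol),
                              error = function(e) {
        warning("skipping unreadable RT-STRUCT: ", conditionMessage(e),
                call. = FALSE)
        list()
      })
      for (s in raw_structs) {
        if (all(s$mask == 0)) {
          warning("dropping empty structure '", s$name, "'", call. = FALSE)
          next
        }
        structures[[length(structures) + 1L]] <- s
        attr(structures[[length(structures)]], "source_file") <- rs_files[[1L]]
      }
    }
  }
  ss <- structure_set(pid, structures)
  body <- tryCatch(which_body(ss), error = function(e) NA_integer_)
  ss$body_index <- body
  list(volume = vol, structures = ss)
}

# Index of the body structure ("BODY" or "External", case-insensitive).
which_body <- function(ss) {
  nms <- tolower(structure_names(ss))
  hits <- which(nms %in% c("body", "external"))
  if (length(hits) == 0L)
    stop("no body structure (named 'BODY' or 'External') found")
  if (length(hits) > 1L)
    warning("multiple body candidates (",
            paste(structure_names(ss)[hits], collapse = ", "),
            "); taking the first by file order", call. = FALSE)
  hits[1L]
}

#' Find the body structure of a structure set
#'
#' The body is the structure named `"BODY"` or `"External"`
#' (case-insensitive). With multiple candidates the first in file order
#' wins, with a warning; with none, an error is raised.
#'
#' @param ss a [structure_set()].
#' @return the body [named_structure()]; as a side effect the returned
#'   set ordering is untouched (use `which_body` semantics via
#'   `attr(, "index")` if the position is needed).
#' @export
find_body <- function(ss) {
  if (length(ss$structures) == 0L) stop("structure set is empty")
  i <- which_body(ss)
  out <- ss$structures[[i]]
  attr(out, "index") <- i
  out
}

#' Copy a structure file into a class-sorted output tree
#'
#' Copies the structure's source file unmodified to
#' `<out_root>/<class_label>/<patient_id>/`. Name collisions get a
#' numeric suffix with a warning.
#'
#' @param structure a [named_structure()] carrying a `source_file`
#'   attribute, or a file path.
#' @param class_label final class label (must be in `vocabulary` when
#'   given).
#' @param patient_id patient folder name.
#' @param out_root output root directory.
#' @param vocabulary optional class vocabulary for validation.
#' @return the destination file path.
#' @export
write_structure_copy <- function(structure, class_label, patient_id, out_root,
                                 vocabulary = NULL) {
  if (!is.null(vocabulary) && !(class_label %in% vocabulary))
    stop("class label '", class_label, "' is not in the model vocabulary")
  src <- if (is.character(structure)) structure
         else attr(structure, "source_file")
  if (is.null(src) || !file.exists(src))
    stop("structure has no readable source file to copy")
  dest_dir <- file.path(out_root, class_label, patient_id)
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(dest_dir, basename(src))
  if (file.exists(dest)) {
    base <- sub("(\\.nii(\\.gz)?|\\.dcm)$", "", basename(src))
    ext <- substring(basename(src), nchar(base) + 1L)
    i <- 1L
    repeat {
      cand <- file.path(dest_dir, sprintf("%s_%d%s", base, i, ext))
      if (!file.exists(cand)) break
      i <- i + 1L
    }
    warning("collision for ", basename(src), "; writing ", basename(cand),
            call. = FALSE)
    dest <- cand
  }
  file.copy(src, dest)
  dest
}

#' Write a patient to a NIfTI folder
#'
#' Emits `image.nii.gz` (CT as int16 HU) and one
#' `mask_<StructureName>.nii.gz` per structure, the layout
#' [load_patient()] reads back.
#'
#' @param vol an [image_volume()] in HU.
#' @param ss a [structure_set()] on the same grid.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_patient_nifti <- function(vol, ss, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(vol, file.path(dir, "image.nii.gz"), datatype = 4L)
  for (s in ss$structures) {
    write_nifti(s, file.path(dir, paste0("mask_", s$name, ".nii.gz")),
                spacing = vol$spacing, origin = vol$origin)
  }
  invisible(dir)
}
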