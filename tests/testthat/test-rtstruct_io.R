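# Patient I/O: NIfTI round trips, body identification, sorted copies,
# DICOM cross-format equivalence.

make_patient <- function(seed = 42) {
  generate_phantom(phantom_spec("desk"), seed, patient_id = "p001")
}

test_that("NIfTI round trip preserves masks, spacing and origin", {
  p <- make_patient()
  dir <- withr::local_tempdir()
  write_patient_nifti(p$volume, p$structures, dir)
  got <- load_patient(dir, format = "nifti")
  expect_equal(got$volume$voxels, p$volume$voxels)
  expect_lt(max(abs(got$volume$spacing - p$volume$spacing)), 1e-6)
  expect_lt(max(abs(got$volume$origin - p$volume$origin)), 1e-6)
  expect_setequal(structure_names(got$structures),
                  structure_names(p$structures))
  for (nm in structure_names(p$structures)) {
    a <- got$structures$structures[[
      which(structure_names(got$structures) == nm)]]$mask
    b <- p$structures$structures[[
      which(structure_names(p$structures) == nm)]]$mask
    expect_identical(a, b)
  }
  expect_identical(structure_names(got$structures)[
    got$structures$body_index], "BODY")
})

test_that("empty and unreadable structure files are skipped, missing CT is fatal", {
  p <- make_patient()
  dir <- withr::local_tempdir()
  write_patient_nifti(p$volume, p$structures, dir)
  zero <- array(0L, dim(p$volume$voxels))
  write_nifti(named_structure("Empty", zero),
              file.path(dir, "mask_Empty.nii.gz"),
              spacing = p$volume$spacing)
  writeLines("not a nifti", file.path(dir, "mask_Broken.nii.gz"))
  got <- expect_warning(
    expect_warning(load_patient(dir), "Empty"), "Broken")
  expect_false(any(c("Empty", "Broken") %in%
                     structure_names(got$structures)))
  # missing CT
  dir2 <- withr::local_tempdir()
  write_nifti(p$structures$structures[[2]],
              file.path(dir2, "mask_X.nii.gz"),
              spacing = p$volume$spacing)
  expect_error(load_patient(dir2), "no CT volume")
})

test_that("find_body matches BODY/External case-insensitively", {
  mk <- function(nms) {
    m <- array(1L, c(2, 2, 2))
    structure_set("p", lapply(nms, named_structure, mask = m))
  }
  expect_identical(find_body(mk(c("External", "Bladder")))$name,
                   "External")
  expect_identical(find_body(mk("body"))$name, "body")
  expect_error(find_body(mk(c("Bladder", "Rectum"))), "no body")
  expect_warning(b <- find_body(mk(c("BODY", "External"))), "multiple")
  expect_identical(b$name, "BODY")
  expect_identical(attr(b, "index"), 1L)
})

test_that("write_structure_copy sorts by class and suffixes collisions", {
  src_dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  f <- file.path(src_dir, "mask_Bladder_x.nii.gz")
  writeLines("payload", f)
  voc <- c("Bladder", "Other")
  dest <- write_structure_copy(f, "Bladder", "p01", out, vocabulary = voc)
  expect_true(file.exists(file.path(out, "Bladder", "p01",
                                    "mask_Bladder_x.nii.gz")))
  expect_warning(
    dest2 <- write_structure_copy(f, "Bladder", "p01", out,
                                  vocabulary = voc), "collision")
  expect_match(basename(dest2), "_1")
  dest3 <- write_structure_copy(f, "Other", "p01", out, vocabulary = voc)
  expect_true(file.exists(file.path(out, "Other", "p01",
                                    basename(dest3))))
  expect_error(write_structure_copy(f, "Nope", "p01", out,
                                    vocabulary = voc), "vocabulary")
})

test_that("DICOM and NIfTI paths agree on the same phantom", {
  p <- make_patient(7)
  nd <- withr::local_tempdir(); dd <- withr::local_tempdir()
  write_patient_nifti(p$volume, p$structures, nd)
  write_dicom_patient(p$volume, p$structures, dd)
  via_n <- load_patient(nd, format = "nifti")
  via_d <- load_patient(dd, format = "dicom")
  expect_equal(via_d$volume$voxels, via_n$volume$voxels)
  expect_lt(max(abs(via_d$volume$spacing - via_n$volume$spacing)), 1e-6)
  expect_lt(max(abs(via_d$volume$origin - via_n$volume$origin)), 1e-6)
  for (nm in structure_names(via_n$structures)) {
    a <- via_n$structures$structures[[
      which(structure_names(via_n$structures) == nm)]]$mask
    expect_true(nm %in% structure_names(via_d$structures))
    b <- via_d$structures$structures[[
      which(structure_names(via_d$structures) == nm)]]$mask
    agreement <- mean(a == b)
    expect_gte(agreement, 0.999)
  }
})
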