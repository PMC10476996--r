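# Synthetic pelvic CT phantom factory.
#
# Phantoms emulate the geometry the pipeline needs to see: an air
# background (-1000 HU), an elliptical soft-tissue body with a thin fat
# shell and Gaussian noise, a high-density couch slab outside the body,
# bone-density femoral spheres with shafts, and organ structures
# (bladder, rectum, bowel cavity, femoral heads) in two guideline
# variants. Variant A is the base shape; variant B applies parametric
# in-plane dilation plus inferior/superior extension (for the bladder,
# an in-plane erosion instead, emulating bladder-wall exclusion, so
# B is a subset of A for that organ). Nuisance structures with
# clinical-style names (PTV expansions, rings, optimization helpers)
# carry the ground-truth class "Other". HU values and shapes are
# plumbing for testing, not anatomical claims.

.phantom_hu <- c(air = -1000, soft = 40, fat = -100, bone = 700,
                 couch = 200, bladder = 10, rectum = -30, bowel = 25)

#' Phantom specification
#'
#' @param profile `"desk"` (classification-scale, 48 x 48 x 36 at 6 mm)
#'   or `"demo"` (segmentation-demo scale, 32 x 32 x 24 at 9 mm,
#'   bowel only).
#' @param ... field overrides: `grid` (slices, rows, cols), `spacing`
#'   (mm), `organs` (subset of `"bladder"`, `"rectum"`, `"bowel"`,
#'   `"femur_l"`, `"femur_r"`), `dilation_mm`, `ext_sup`, `ext_inf`
#'   (slices), `bladder_erosion_mm`, `noise_sd` (HU), `nuisance`
#'   (logical), `jitter_scale`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(profile = c("desk", "demo"), ...) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    desk = list(grid = c(36L, 48L, 48L), spacing = c(6, 6, 6),
                organs = c("bladder", "rectum", "bowel",
                           "femur_l", "femur_r"),
                dilation_mm = 6, ext_sup = 4L, ext_inf = 4L,
                bladder_erosion_mm = 6),
    demo = list(grid = c(24L, 32L, 32L), spacing = c(9, 9, 9),
                organs = "bowel",
                dilation_mm = 9, ext_sup = 3L, ext_inf = 3L,
                bladder_erosion_mm = 9))
  spec$profile <- profile
  spec$noise_sd <- 10
  spec$nuisance <- profile == "desk"
  spec$jitter_scale <- 1
  dots <- list(...)
  unknown <- setdiff(names(dots), c("grid", "spacing", "organs",
                                    "dilation_mm", "ext_sup", "ext_inf",
                                    "bladder_erosion_mm", "noise_sd",
                                    "nuisance", "jitter_scale"))
  if (length(unknown)) stop("unknown phantom fields: ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  if (spec$dilation_mm < 0 || spec$ext_sup < 0 || spec$ext_inf < 0)
    stop("variant-B rules must be non-negative")
  class(spec) <- "phantom_spec"
  spec
}

# ---- mask morphology helpers -----------------------------------------

ellipsoid_mask <- function(dims, center, semi) {
  s <- (slice.index(array(0L, dims), 1L) - center[1L]) / semi[1L]
  r <- (slice.index(array(0L, dims), 2L) - center[2L]) / semi[2L]
  cc <- (slice.index(array(0L, dims), 3L) - center[3L]) / semi[3L]
  array(as.integer(s * s + r * r + cc * cc <= 1), dims)
}

cylinder_mask <- function(dims, slices, center_rc, radius_rc) {
  r <- (slice.index(array(0L, dims), 2L) - center_rc[1L]) / radius_rc[1L]
  cc <- (slice.index(array(0L, dims), 3L) - center_rc[2L]) / radius_rc[2L]
  m <- array(as.integer(r * r + cc * cc <= 1), dims)
  keep <- array(0L, dims)
  keep[max(1L, slices[1L]):min(dims[1L], slices[2L]), , ] <- 1L
  m * keep
}

# Shift a 3D array by (ds, dr, dc), zero-filling.
shift3d <- function(m, ds, dr, dc) {
  d <- dim(m)
  out <- array(0L, d)
  src <- function(n, k) {
    s <- max(1L, 1L - k):min(d[n], d[n] - k)
    s
  }
  s1 <- src(1L, ds); s2 <- src(2L, dr); s3 <- src(3L, dc)
  if (!length(s1) || !length(s2) || !length(s3)) return(out)
  out[s1 + ds, s2 + dr, s3 + dc] <- m[s1, s2, s3]
  out
}

# In-plane (row/col) dilation by a disc of `r_vox` voxels.
dilate_inplane <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  out <- mask
  rr <- floor(r_vox)
  for (dr in -rr:rr) for (dc in -rr:rr) {
    if (dr == 0L && dc == 0L) next
    if (dr * dr + dc * dc <= r_vox * r_vox)
      out <- pmax(out, shift3d(mask, 0L, dr, dc))
  }
  out
}

erode_inplane <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  1L - dilate_inplane(1L - mask, r_vox)
}

# Extend a mask along the slice axis by copying the terminal nonzero
# slice outward.
extend_slices <- function(mask, ext_sup, ext_inf) {
  nz <- nonzero_slices(mask)
  d <- dim(mask)
  out <- mask
  top <- max(nz); bot <- min(nz)
  if (ext_sup > 0L) for (k in seq_len(ext_sup)) {
    tgt <- top + k
    if (tgt > d[1L]) break
    out[tgt, , ] <- pmax(out[tgt, , ], mask[top, , ])
  }
  if (ext_inf > 0L) for (k in seq_len(ext_inf)) {
    tgt <- bot - k
    if (tgt < 1L) break
    out[tgt, , ] <- pmax(out[tgt, , ], mask[bot, , ])
  }
  out
}

apply_variant_b <- function(mask, organ, spec) {
  r_vox <- spec$dilation_mm / spec$spacing[2L]
  if (organ == "bladder") {
    e_vox <- spec$bladder_erosion_mm / spec$spacing[2L]
    return(erode_inplane(mask, e_vox))
  }
  out <- dilate_inplane(mask, r_vox)
  extend_slices(out, spec$ext_sup, spec$ext_inf)
}

.organ_class_names <- list(
  bladder = c(A = "Bladder", B = "Bladder_AI1"),
  rectum  = c(A = "Rectum", B = "Anorectum_AI1"),
  bowel   = c(A = "Bowel_Dev", B = "Bowel_RTOG"),
  femur_l = c(A = "FemoralHead_L", B = "Femur_Head_L_AI1"),
  femur_r = c(A = "FemoralHead_R", B = "Femur_Head_R_AI1"))

#' Class vocabulary of the desk phantom world
#'
#' Ordered class list for the desk-scale cohort; mirrors the paper-style
#' per-organ, per-guideline naming and ends with `"Other"`.
#' @param organs organ subset, as in [phantom_spec()].
#' @return character vector of class names.
#' @export
phantom_vocabulary <- function(organs = c("bladder", "rectum", "bowel",
                                          "femur_l", "femur_r")) {
  c(as.vector(vapply(organs, function(o) .organ_class_names[[o]],
                     character(2))), "Other")
}

# Base (variant A) organ geometry for one patient, in voxel units.
phantom_geometry <- function(spec, jit) {
  d <- spec$grid
  ctr_r <- d[2L] / 2 + 1 + jit("body_r", 1)
  ctr_c <- d[3L] / 2 + 0.5 + jit("body_c", 1)
  body_semi <- c(d[2L] * 0.345, d[3L] * 0.42) *
    (1 + jit("body_s", 0.04))
  g <- list(body_center = c(ctr_r, ctr_c), body_semi = body_semi)
  s_mid <- d[1L] / 2
  og <- list(
    bladder = list(center = c(s_mid, ctr_r + d[2L] * 0.06, ctr_c),
                   semi = c(d[1L] * 0.11, d[2L] * 0.105, d[3L] * 0.105)),
    bowel   = list(center = c(s_mid * 1.5, ctr_r - d[2L] * 0.06, ctr_c),
                   semi = c(d[1L] * 0.17, d[2L] * 0.145, d[3L] * 0.165)),
    rectum  = list(slices = round(c(s_mid * 0.45, s_mid * 1.1)),
                   center = c(ctr_r + d[2L] * 0.19, ctr_c),
                   radius = c(d[2L] * 0.042, d[3L] * 0.042) + 1),
    femur_l = list(center = c(s_mid * 0.67, ctr_r + d[2L] * 0.06,
                              ctr_c - d[3L] * 0.26),
                   semi = rep(d[2L] * 0.052 + 0.8, 3L)),
    femur_r = list(center = c(s_mid * 0.67, ctr_r + d[2L] * 0.06,
                              ctr_c + d[3L] * 0.26),
                   semi = rep(d[2L] * 0.052 + 0.8, 3L)))
  for (o in names(og)) {
    if (!is.null(og[[o]]$center))
      og[[o]]$center <- og[[o]]$center + jit(paste0(o, "_ctr"), 1.2)
    if (!is.null(og[[o]]$semi))
      og[[o]]$semi <- og[[o]]$semi * (1 + jit(paste0(o, "_s"), 0.08))
  }
  g$organs <- og
  g
}

#' Generate one synthetic pelvic phantom
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the phantom is a pure function of
#'   `(spec, seed)`.
#' @param patient_id identifier for the emitted structure set.
#' @return list with `volume` (HU [image_volume()]), `structures`
#'   ([structure_set()], body first) and `labels` (named character
#'   vector mapping structure names to true classes).
#' @export
generate_phantom <- function(spec, seed, patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  d <- spec$grid
  for (attempt in 1:5) {
    jit <- local({
      cache <- list()
      function(key, scale) {
        if (is.null(cache[[key]]))
          cache[[key]] <<- runif(1, -1, 1) * scale * spec$jitter_scale
        cache[[key]]
      }
    })
    g <- phantom_geometry(spec, jit)
    # body: in-plane ellipse through all slices
    body <- cylinder_mask(d, c(1L, d[1L]), g$body_center, g$body_semi)
    organs_a <- list(); organs_b <- list(); ok <- TRUE
    for (o in spec$organs) {
      go <- g$organs[[o]]
      a <- if (o == "rectum")
        cylinder_mask(d, go$slices, go$center, go$radius)
      else ellipsoid_mask(d, go$center, go$semi)
      b <- apply_variant_b(a, o, spec)
      if (any(b == 1L & body == 0L) || sum(a) == 0L) { ok <- FALSE; break }
      organs_a[[o]] <- a; organs_b[[o]] <- b
    }
    if (ok) break
    if (attempt == 5L) stop("phantom organs collide with the body; ",
                            "spec geometry infeasible")
  }
  # CT image
  hu <- .phantom_hu
  ct <- array(hu["air"], d)
  fat_shell <- body - erode_inplane(body, 1)
  ct[body == 1L] <- hu["soft"]
  ct[fat_shell == 1L] <- hu["fat"]
  for (o in intersect(c("bladder", "rectum", "bowel"), names(organs_a)))
    ct[organs_a[[o]] == 1L] <- hu[[o]]
  for (o in intersect(c("femur_l", "femur_r"), names(organs_a))) {
    ct[organs_a[[o]] == 1L] <- hu["bone"]
    go <- g$organs[[o]]
    shaft <- cylinder_mask(d, c(1L, round(go$center[1L])),
                           go$center[2:3], pmax(1, go$semi[2:3] * 0.6))
    ct[shaft == 1L & body == 1L] <- hu["bone"]
  }
  # couch slab posterior to the body, clear of its jittered extent
  couch <- array(0L, d)
  body_max_row <- max(which(apply(body == 1L, 2L, any)))
  couch_start <- body_max_row + 2L
  if (couch_start + 1L > d[2L]) couch_start <- body_max_row + 1L
  if (couch_start + 1L <= d[2L]) {
    couch[, couch_start:(couch_start + 1L),
          round(d[3L] * 0.15):round(d[3L] * 0.85)] <- 1L
    if (any(couch == 1L & body == 1L)) stop("couch intersects body")
    ct[couch == 1L] <- hu["couch"]
  }
  # noise on tissue only: scanner-calibrated air sits exactly at the
  # -1000 HU floor, which is what the z-score air threshold relies on
  noisy <- ct > .phantom_hu[["air"]]
  ct[noisy] <- round(ct[noisy] + rnorm(sum(noisy), 0, spec$noise_sd))
  vol <- image_volume(ct, spec$spacing, origin = c(0, 0, 0))

  structures <- list(named_structure("BODY", body))
  labels <- c(BODY = "Other")
  for (o in spec$organs) {
    nms <- .organ_class_names[[o]]
    structures <- c(structures,
                    list(named_structure(nms[["A"]], organs_a[[o]]),
                         named_structure(nms[["B"]], organs_b[[o]])))
    labels[nms[["A"]]] <- nms[["A"]]
    labels[nms[["B"]]] <- nms[["B"]]
  }
  if (isTRUE(spec$nuisance) && "bladder" %in% spec$organs) {
    bl <- organs_a$bladder
    ptv <- dilate_inplane(bl, 2) * body
    ring <- (dilate_inplane(bl, 3.5) - dilate_inplane(bl, 2)) * body
    blob_ctr <- c(d[1L] * 0.75, g$body_center[1L] - d[2L] * 0.02,
                  g$body_center[2L] + d[3L] * 0.17) +
      jit("blob_ctr", 1.5) * c(1, 1, 1)
    blob <- ellipsoid_mask(d, blob_ctr,
                           c(d[1L] * 0.2, d[2L] * 0.035, d[3L] * 0.035) +
                             0.5) * body
    ptv_name <- sample(c("PTV_68", "PTV_boost", "CTV_bladder"), 1L)
    ring_name <- sample(c("Ring_PTV", "ring_dose", "Opt_ring"), 1L)
    for (nm in list(c(ptv_name, "ptv"), c(ring_name, "ring"),
                    c("Vessels", "blob"))) {
      m <- switch(nm[2L], ptv = ptv, ring = ring, blob = blob)
      if (sum(m) > 0L) {
        structures <- c(structures, list(named_structure(nm[1L], m)))
        labels[nm[1L]] <- "Other"
      }
    }
  }
  ss <- structure_set(patient_id, structures, body_index = 1L)
  list(volume = vol, structures = ss, labels = labels)
}

#' Generate a phantom cohort
#'
#' Per-patient morphological jitter and noise are driven by seeds drawn
#' deterministically from `base_seed`. With `dir` given, each patient
#' is written as a NIfTI folder ([write_patient_nifti()]) plus a
#' cohort-level `manifest.csv` (patient id, structure name, true
#' class); otherwise patients are returned in memory.
#'
#' @param n number of patients (`>= 1`).
#' @param spec a [phantom_spec()].
#' @param base_seed integer cohort seed.
#' @param dir optional output directory.
#' @return invisibly (with `dir`) or visibly (in memory) a list with
#'   `patients` (list or character paths) and `manifest` (data frame).
#' @export
generate_cohort <- function(n, spec, base_seed, dir = NULL) {
  stopifnot(n >= 1)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("patient%03d", seq_len(n))
  patients <- vector("list", n)
  manifest <- list()
  for (i in seq_len(n)) {
    p <- generate_phantom(spec, seeds[i], patient_id = ids[i])
    manifest[[i]] <- data.frame(patient_id = ids[i],
                                structure = names(p$labels),
                                class = unname(p$labels))
    if (is.null(dir)) {
      patients[[i]] <- p
    } else {
      pd <- file.path(dir, ids[i])
      write_patient_nifti(p$volume, p$structures, pd)
      patients[[i]] <- pd
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    invisible(list(patients = unlist(patients), manifest = manifest))
  } else {
    list(patients = patients, manifest = manifest)
  }
}
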