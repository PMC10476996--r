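# Preprocessing chain: CT + one structure -> fixed-size two-channel
# classifier input (normalized CT + AddMap).
#
# Order of operations is fixed: z-score normalize (statistics from
# voxels above the air threshold, before resampling) -> resample to the
# profile spacing -> remove everything outside the body -> crop to the
# body bounding box -> AddMap -> slice-count eligibility -> structure-
# centered slice window -> symmetric zero-fill (or, at inference only,
# in-plane downscale) to the profile grid.

#' Preprocessing configuration
#'
#' Three named profiles ship with the package. `"bowel"` and `"pelvis"`
#' carry the clinical-scale values: 2 x 2 mm in-plane / 3 mm slice
#' spacing, a 96-slice cap (96 x 3 mm = 288 mm inferior-superior
#' support) and target grids of 184 x 280 x 96 and 200 x 328 x 96
#' voxels respectively. `"desk"` is a reduced phantom-scale profile
#' (6 mm isotropic, 24-slice cap, 40 x 44 x 24 grid) sized for CPU-only
#' testing.
#'
#' @param profile `"bowel"`, `"pelvis"` or `"desk"`.
#' @param ... overrides for individual fields (`target_spacing`,
#'   `slice_cap`, `target_grid`, `air_threshold`, `allow_downscale`).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(profile = c("bowel", "pelvis", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    bowel = list(target_spacing = c(3, 2, 2), slice_cap = 96L,
                 target_grid = c(184L, 280L, 96L)),
    pelvis = list(target_spacing = c(3, 2, 2), slice_cap = 96L,
                  target_grid = c(200L, 328L, 96L)),
    desk = list(target_spacing = c(6, 6, 6), slice_cap = 24L,
                target_grid = c(40L, 44L, 24L)))
  cfg$profile <- profile
  cfg$air_threshold <- -1000
  cfg$allow_downscale <- FALSE
  dots <- list(...)
  unknown <- setdiff(names(dots), c("target_spacing", "slice_cap",
                                    "target_grid", "air_threshold",
                                    "allow_downscale"))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$target_grid[3L] != cfg$slice_cap)
    stop("target grid slice count must equal the slice cap")
  class(cfg) <- "preprocess_config"
  cfg
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf(paste0("<preprocess_config> profile '%s': spacing %s mm, ",
                     "slice cap %d, grid %s, air threshold %g HU\n"),
              x$profile, paste(x$target_spacing, collapse = "x"),
              x$slice_cap, paste(x$target_grid, collapse = "x"),
              x$air_threshold))
  invisible(x)
}

#' Z-score normalize a CT volume
#'
#' Mean and standard deviation are computed only over voxels strictly
#' above the air threshold (default -1000 HU), then applied to every
#' voxel. The population standard deviation is used.
#'
#' @param ct an [image_volume()] in HU.
#' @param air_threshold HU threshold; voxels at or below it are
#'   excluded from the statistics.
#' @return normalized [image_volume()].
#' @export
zscore_normalize <- function(ct, air_threshold = -1000) {
  v <- ct$voxels
  sel <- v > air_threshold
  n <- sum(sel)
  if (n < 2L) stop("fewer than 2 voxels above the air threshold")
  mu <- mean(v[sel])
  sigma <- sqrt(sum((v[sel] - mu)^2) / n)
  if (sigma == 0) stop("degenerate volume: zero intensity spread above air")
  out <- ct
  out$voxels <- (v - mu) / sigma
  attr(out, "norm_stats") <- c(mean = mu, sd = sigma)
  out
}

as_mask_array <- function(x) {
  m <- if (inherits(x, "named_structure")) x$mask else x
  if (!is.array(m) || length(dim(m)) != 3L) stop("mask must be a 3D array")
  m
}

#' Zero everything outside the body
#'
#' @param ct an [image_volume()] (any intensity scale) or 3D array.
#' @param body body mask ([named_structure()] or binary array),
#'   congruent grid.
#' @return same type as `ct`, with voxels outside the body set to 0.
#' @export
mask_outside_body <- function(ct, body) {
  b <- as_mask_array(body)
  arr <- if (inherits(ct, "image_volume")) ct$voxels else ct
  if (!identical(dim(arr), dim(b))) stop("CT and body grids differ")
  if (all(b == 0)) stop("body mask is empty")
  out <- arr * (b != 0)
  if (inherits(ct, "image_volume")) { ct$voxels <- out; ct } else out
}

#' Crop a volume to the body bounding box
#'
#' @param volume an [image_volume()] or 3D array.
#' @param body body mask on the same grid (or a precomputed bbox as
#'   returned by the `"bbox"` attribute of an earlier call).
#' @return cropped volume/array; the applied bbox (list of index
#'   ranges, `(slice, row, col)`) is attached as attribute `"bbox"`.
#' @export
crop_to_body <- function(volume, body) {
  bb <- if (is.list(body) && !inherits(body, "named_structure")) body
        else mask_bbox(as_mask_array(body))
  arr <- if (inherits(volume, "image_volume")) volume$voxels else volume
  out <- arr[bb[[1L]][1L]:bb[[1L]][2L],
             bb[[2L]][1L]:bb[[2L]][2L],
             bb[[3L]][1L]:bb[[3L]][2L], drop = FALSE]
  if (inherits(volume, "image_volume")) {
    volume$voxels <- out
    volume$origin <- volume$origin +
      (vapply(bb, `[`, numeric(1), 1L) - 1) * volume$spacing
    attr(volume, "bbox") <- bb
    volume
  } else {
    attr(out, "bbox") <- bb
    out
  }
}

#' Build the AddMap joint encoding
#'
#' `(body + structure) / 2`: 1 where body and structure overlap, 0.5
#' inside the body only, 0 in the background. Structure voxels outside
#' the body (not expected after body masking) also yield 0.5 and are
#' flagged with a warning.
#'
#' @param body_mask,structure_mask congruent binary 3D arrays.
#' @return numeric 3D array with values in `{0, 0.5, 1}`.
#' @export
make_addmap <- function(body_mask, structure_mask) {
  b <- as_mask_array(body_mask); s <- as_mask_array(structure_mask)
  if (!identical(dim(b), dim(s))) stop("body and structure grids differ")
  if (!all(b %in% c(0, 1)) || !all(s %in% c(0, 1)))
    stop("AddMap inputs must be binary")
  if (any(s == 1 & b == 0))
    warning("structure extends outside the body mask", call. = FALSE)
  (b + s) / 2
}

#' Slice-count eligibility of a structure
#'
#' A structure is eligible when the number of 2D slices containing any
#' nonzero voxel does not exceed the slice cap (96 slices x 3 mm =
#' 288 mm inferior-superior support on the clinical profiles; the rule
#' is strict, so exactly `slice_cap` nonzero slices is still eligible).
#'
#' @param structure_mask binary 3D array, `(slice, row, col)`.
#' @param slice_cap maximum number of nonzero slices.
#' @return `TRUE` if eligible.
#' @export
slice_eligibility <- function(structure_mask, slice_cap) {
  length(nonzero_slices(as_mask_array(structure_mask))) <= slice_cap
}

#' Structure-centered slice window
#'
#' The center slice is the midpoint between the first and last nonzero
#' slice (rounded up at half-slices); the window spans `slice_cap`
#' slices centered there (`center - cap/2` to `center + cap/2`, half
#' open). Rounding up is what keeps every nonzero slice inside the
#' window when the structure's extent equals the cap exactly. Parts of
#' the window outside the volume are zero-filled by
#' [extract_window()], not shifted.
#'
#' @param structure_mask binary 3D array.
#' @param slice_cap window length in slices.
#' @return integer `c(start, end)`, a closed 1-based slice range of
#'   exactly `slice_cap` slices (may extend beyond the volume).
#' @export
center_window <- function(structure_mask, slice_cap) {
  nz <- nonzero_slices(as_mask_array(structure_mask))
  if (length(nz) == 0L) stop("empty structure has no window")
  c0 <- as.integer(ceiling((min(nz) - 1L + max(nz) - 1L) / 2))  # 0-based
  start <- c0 - slice_cap %/% 2L + 1L          # back to 1-based
  c(start, start + slice_cap - 1L)
}

#' Extract a slice window, zero-filling outside the volume
#'
#' @param arr 3D array, `(slice, row, col)`.
#' @param window `c(start, end)` 1-based closed slice range.
#' @return array of `end - start + 1` slices.
#' @export
extract_window <- function(arr, window) {
  d <- dim(arr)
  n <- window[2L] - window[1L] + 1L
  out <- array(0, c(n, d[2L], d[3L]))
  src <- max(1L, window[1L]):min(d[1L], window[2L])
  if (length(src) > 0L && src[1L] <= src[length(src)])
    out[src - window[1L] + 1L, , ] <- arr[src, , , drop = FALSE]
  out
}

#' Pad (or, at inference, downscale) to the target grid
#'
#' Smaller dimensions are symmetrically zero-filled, the odd remainder
#' going to the high-index side. An in-plane dimension larger than the
#' target is an error during training; at inference
#' (`allow_downscale = TRUE`) the in-plane axes are downscaled to the
#' target by nearest-neighbor lookup (so AddMap values stay in
#' `{0, 0.5, 1}`). The slice axis is never downscaled.
#'
#' @param channel 3D array, `(slice, row, col)`.
#' @param target_grid integer `c(rows, cols, slices)`.
#' @param allow_downscale logical.
#' @return array of dimension `(slices, rows, cols)` per `target_grid`.
#' @export
pad_or_downscale <- function(channel, target_grid, allow_downscale = FALSE) {
  d <- dim(channel)
  want <- c(target_grid[3L], target_grid[1L], target_grid[2L])  # (s,r,c)
  if (d[1L] > want[1L])
    stop("structure window exceeds the target slice count")
  if (any(d[2:3] > want[2:3])) {
    if (!allow_downscale)
      stop("in-plane size ", d[2L], "x", d[3L], " exceeds target ",
           want[2L], "x", want[3L], " (downscaling disabled in training)")
    idx_r <- pmin(d[2L], pmax(1L, ceiling(seq_len(want[2L]) * d[2L] /
                                            want[2L] - 0.5)))
    idx_c <- pmin(d[3L], pmax(1L, ceiling(seq_len(want[3L]) * d[3L] /
                                            want[3L] - 0.5)))
    channel <- channel[, idx_r, idx_c, drop = FALSE]
    d <- dim(channel)
  }
  pad <- want - d
  lo <- pad %/% 2L            # odd remainder goes to the high side
  out <- array(0, want)
  out[lo[1L] + seq_len(d[1L]),
      lo[2L] + seq_len(d[2L]),
      lo[3L] + seq_len(d[3L])] <- channel
  out
}

#' Two-channel classifier sample
#'
#' @param ct,addmap congruent 3D arrays on the target grid.
#' @param name structure name.
#' @param label class label or `NA` when unknown.
#' @param patient_id optional patient identifier.
#' @return a `classifier_sample`.
#' @export
classifier_sample <- function(ct, addmap, name, label = NA_character_,
                              patient_id = NA_character_) {
  if (!identical(dim(ct), dim(addmap)))
    stop("CT and AddMap channels must share one grid")
  if (!all(addmap %in% c(0, 0.5, 1)))
    stop("AddMap values must lie in {0, 0.5, 1}")
  structure(list(ct = ct, addmap = addmap, name = name, label = label,
                 patient_id = patient_id),
            class = "classifier_sample")
}

#' Assemble one classifier sample from CT, body and structure
#'
#' Runs the full preprocessing chain in the fixed order. Returns `NULL`
#' (with a message) when the structure exceeds the slice cap.
#'
#' @param ct raw CT [image_volume()] in HU.
#' @param body body [named_structure()] on the CT grid.
#' @param structure the structure to encode, on the CT grid.
#' @param config a [preprocess_config()].
#' @param label optional class label carried on the sample.
#' @param precomputed optional cached output of
#'   [preprocess_patient_ct()] for this CT/body pair.
#' @return a [classifier_sample()] or `NULL` if ineligible.
#' @export
assemble_sample <- function(ct, body, structure, config,
                            label = NA_character_, precomputed = NULL) {
  pc <- if (is.null(precomputed)) preprocess_patient_ct(ct, body, config)
        else precomputed
  s_rs <- resample(structure$mask, config$target_spacing, mode = "mask",
                   spacing = ct$spacing)
  s_rs <- s_rs * (pc$body_rs != 0)       # volume masking, as for the CT
  if (all(s_rs == 0)) {
    message("structure '", structure$name, "' empty after body masking; skip")
    return(NULL)
  }
  s_c <- crop_to_body(s_rs, pc$bbox)
  if (!slice_eligibility(s_c, config$slice_cap)) {
    message("structure '", structure$name, "' spans more than ",
            config$slice_cap, " slices; ignored")
    return(NULL)
  }
  addmap <- make_addmap(pc$body_c, s_c)
  win <- center_window(s_c, config$slice_cap)
  ct_w <- extract_window(pc$ct_c, win)
  am_w <- extract_window(addmap, win)
  classifier_sample(
    ct = pad_or_downscale(ct_w, config$target_grid, config$allow_downscale),
    addmap = pad_or_downscale(am_w, config$target_grid,
                              config$allow_downscale),
    name = structure$name, label = label)
}

#' Patient-level CT preprocessing (shared across structures)
#'
#' Normalizes, resamples, body-masks and crops the CT once; the result
#' can be passed to [assemble_sample()] via `precomputed` for each
#' structure of the patient.
#'
#' @inheritParams assemble_sample
#' @return list with `ct_c` (cropped normalized CT array), `body_c`
#'   (cropped body mask), `body_rs` (resampled body mask, uncropped)
#'   and `bbox`.
#' @export
preprocess_patient_ct <- function(ct, body, config) {
  ct_n <- zscore_normalize(ct, config$air_threshold)
  ct_rs <- resample(ct_n, config$target_spacing, mode = "intensity")
  body_rs <- resample(body$mask, config$target_spacing, mode = "mask",
                      spacing = ct$spacing)
  if (all(body_rs == 0)) stop("body mask empty after resampling")
  ct_rs <- mask_outside_body(ct_rs, body_rs)
  bbox <- mask_bbox(body_rs)
  list(ct_c = crop_to_body(ct_rs$voxels, bbox),
       body_c = crop_to_body(body_rs, bbox),
       body_rs = body_rs, bbox = bbox)
}

#' Preprocess every structure of a patient
#'
#' @param vol raw CT [image_volume()].
#' @param ss a [structure_set()] with a designated body.
#' @param config a [preprocess_config()].
#' @param labels optional named character vector mapping structure
#'   names to class labels.
#' @return list of [classifier_sample()]s (ineligible structures are
#'   skipped with a message and recorded in attribute `"skipped"`).
#' @export
preprocess_patient <- function(vol, ss, config, labels = NULL) {
  if (is.na(ss$body_index)) stop("structure set has no designated body")
  body <- ss$structures[[ss$body_index]]
  pc <- preprocess_patient_ct(vol, body, config)
  samples <- list(); skipped <- character(0)
  for (i in seq_along(ss$structures)) {
    if (i == ss$body_index) next
    s <- ss$structures[[i]]
    lbl <- if (!is.null(labels) && s$name %in% names(labels))
      labels[[s$name]] else NA_character_
    smp <- assemble_sample(vol, body, s, config, label = lbl,
                           precomputed = pc)
    if (is.null(smp)) { skipped <- c(skipped, s$name); next }
    smp$patient_id <- ss$patient_id
    attr(smp, "source_file") <- attr(s, "source_file")
    samples[[length(samples) + 1L]] <- smp
  }
  attr(samples, "skipped") <- skipped
  samples
}
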