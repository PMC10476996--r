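# Minimal DICOM codec (explicit VR little endian).
#
# Scope: enough of the standard to round-trip what the phantom exporter
# writes — a single-frame CT series plus an RT-STRUCT with
# CLOSED_PLANAR contour sequences. This is deliberately not a general
# DICOM implementation (no pydicom-equivalent exists in the installed
# stack); unsupported inputs fail loudly rather than guess.

.dcm_uid_root <- "1.2.826.0.1.3680043.10.1073"

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- function(suffix) paste(.dcm_uid_root, suffix, sep = ".")

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
raw_uint32 <- function(x) {
  # writeBin has no unsigned 32-bit: values here stay < 2^31
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

dcm_pad <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

# Encode one data element. `value` is raw for OB/OW, character for
# string VRs, integer vector for US/UL, list of raw item bodies for SQ.
dcm_element <- function(group, elem, vr, value) {
  body <- switch(vr,
    US = raw_uint16(value),
    UL = raw_uint32(value),
    OB = ,
    OW = value,
    SQ = {
      items <- lapply(value, function(it)
        c(raw_uint16(c(0xFFFE, 0xE000)), raw_uint32(length(it)), it))
      do.call(c, items)
    },
    {
      v <- charToRaw(paste(value, collapse = "\\"))
      dcm_pad(v, pad = if (vr == "UI") as.raw(0x00) else as.raw(0x20))
    })
  if (is.null(body)) body <- raw(0)
  hdr <- c(raw_uint16(c(group, elem)), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(hdr, raw(2L), raw_uint32(length(body)), body)
  } else {
    c(hdr, raw_uint16(length(body)), body)
  }
}

dcm_ds <- function(x) {
  # DS: decimal string, max 16 bytes per value
  vapply(x, function(v) formatC(v, format = "g", digits = 10, width = 1),
         character(1))
}

dcm_file_meta <- function(sop_class, sop_instance) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002, 0x0012, "UI", dcm_uid("0"))
  )
  c(raw(128L), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
}

dcm_write_file <- function(path, sop_class, sop_instance, dataset) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(dcm_file_meta(sop_class, sop_instance), dataset), con)
  invisible(path)
}

#' Export a CT volume and structure set as DICOM
#'
#' Writes one explicit-VR little-endian CT file per slice
#' (`CT_<k>.dcm`) and a single RT-STRUCT (`RS.dcm`) whose contours are
#' traced from the binary masks at the 0.5 iso-level. The x/y/z patient
#' axes map to the package's column/row/slice axes.
#'
#' @param vol an [image_volume()] in Hounsfield units.
#' @param structs a [structure_set()] on the same grid.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_patient <- function(vol, structs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$voxels)
  sp <- vol$spacing; or <- vol$origin
  series_uid <- dcm_uid("1.1")
  study_uid <- dcm_uid("1")
  ct_sop <- "1.2.840.10008.5.1.4.1.1.2"
  for (k in seq_len(d[1L])) {
    sop_instance <- dcm_uid(paste0("1.1.", k))
    slice <- vol$voxels[k, , ]                  # row x col
    pix <- as.integer(round(t(slice)))          # col fastest
    z <- or[1L] + (k - 1L) * sp[1L]
    dataset <- c(
      dcm_element(0x0008, 0x0016, "UI", ct_sop),
      dcm_element(0x0008, 0x0018, "UI", sop_instance),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0010, 0x0020, "LO", structs$patient_id),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(c(or[3L], or[2L], z))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2L]),
      dcm_element(0x0028, 0x0011, "US", d[3L]),
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(sp[2L], sp[3L]))),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(sp[1L])),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(pix, raw(), size = 2L, endian = "little"))
    )
    dcm_write_file(file.path(dir, sprintf("CT_%04d.dcm", k)),
                   ct_sop, sop_instance, dataset)
  }
  rs_sop <- "1.2.840.10008.5.1.4.1.1.481.3"
  rs_instance <- dcm_uid("2.1")
  roi_items <- list(); contour_items <- list()
  for (i in seq_along(structs$structures)) {
    s <- structs$structures[[i]]
    roi_items[[i]] <- c(
      dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0026, "LO", s$name)
    )
    polys <- mask_to_contours(s$mask, sp, or)
    citems <- lapply(polys, function(p) {
      xyz <- as.vector(rbind(p$x, p$y, p$z))   # x=col, y=row, z=slice mm
      c(dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(length(p$x))),
        dcm_element(0x3006, 0x0050, "DS", dcm_ds(xyz)))
    })
    contour_items[[i]] <- c(
      if (length(citems)) dcm_element(0x3006, 0x0040, "SQ", citems),
      dcm_element(0x3006, 0x0084, "IS", as.character(i))
    )
  }
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", rs_sop),
    dcm_element(0x0008, 0x0018, "UI", rs_instance),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x0010, 0x0020, "LO", structs$patient_id),
    dcm_element(0x0020, 0x000D, "UI", study_uid),
    dcm_element(0x3006, 0x0020, "SQ", roi_items),
    dcm_element(0x3006, 0x0039, "SQ", contour_items)
  )
  dcm_write_file(file.path(dir, "RS.dcm"), rs_sop, rs_instance, dataset)
  invisible(dir)
}

# ---- reading ----------------------------------------------------------

# Parse one explicit-VR-LE dataset from raw vector `buf` starting at
# byte offset `pos` (1-based), stopping at `end`. Returns list(elements,
# pos). SQ values are parsed recursively into lists of item datasets.
dcm_parse_dataset <- function(buf, pos, end) {
  u16 <- function(p) readBin(buf[p:(p + 1L)], "integer", size = 2L,
                             signed = FALSE, endian = "little")
  u32 <- function(p) {
    v <- readBin(buf[p:(p + 3L)], "integer", size = 4L, endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
  out <- list()
  while (pos <= end) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group == 0xFFFE && elem == 0xE00D) {       # item delimiter
      pos <- pos + 8L
      return(list(elements = out, pos = pos, item_end = TRUE))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    tag <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      if (len == 2^32 - 1) {                        # undefined length
        repeat {
          ig <- u16(pos); ie <- u16(pos + 2L)
          if (ig == 0xFFFE && ie == 0xE0DD) { pos <- pos + 8L; break }
          if (!(ig == 0xFFFE && ie == 0xE000))
            stop("malformed sequence in DICOM stream")
          ilen <- u32(pos + 4L); pos <- pos + 8L
          if (ilen == 2^32 - 1) {
            r <- dcm_parse_dataset(buf, pos, end)
            items[[length(items) + 1L]] <- r$elements; pos <- r$pos
          } else {
            r <- dcm_parse_dataset(buf, pos, pos + ilen - 1L)
            items[[length(items) + 1L]] <- r$elements; pos <- pos + ilen
          }
        }
      } else {
        sq_end <- pos + len - 1L
        while (pos < sq_end) {
          ig <- u16(pos); ie <- u16(pos + 2L)
          if (!(ig == 0xFFFE && ie == 0xE000))
            stop("malformed sequence in DICOM stream")
          ilen <- u32(pos + 4L); pos <- pos + 8L
          r <- dcm_parse_dataset(buf, pos, pos + ilen - 1L)
          items[[length(items) + 1L]] <- r$elements
          pos <- pos + ilen
        }
      }
      out[[tag]] <- list(vr = vr, value = items)
    } else {
      val <- if (len > 0L) buf[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[tag]] <- list(vr = vr, value = val)
    }
  }
  list(elements = out, pos = pos, item_end = FALSE)
}

dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 160L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # file meta: first element must be (0002,0000) UL group length
  if (readBin(buf[133:134], "integer", size = 2L, signed = FALSE,
              endian = "little") != 2L)
    stop("missing file meta group length: ", path)
  meta_len <- readBin(buf[141:144], "integer", size = 4L, endian = "little")
  meta <- dcm_parse_dataset(buf, 145L, 144L + meta_len)
  ds_start <- 145L + meta_len
  ts <- meta$elements[["0002,0010"]]
  if (!is.null(ts) && dcm_string(ts) != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax in ", path)
  dcm_parse_dataset(buf, ds_start, length(buf))$elements
}

dcm_string <- function(el) {
  v <- el$value
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}
dcm_strings <- function(el) strsplit(dcm_string(el), "\\", fixed = TRUE)[[1L]]
dcm_numeric <- function(el) as.numeric(dcm_strings(el))
dcm_us <- function(el) readBin(el$value, "integer", size = 2L,
                               signed = FALSE, endian = "little")

# Read a DICOM CT series (one file per slice) from `files`.
dcm_read_ct_series <- function(files) {
  slices <- lapply(files, dcm_read_file)
  ipp <- t(vapply(slices, function(e) dcm_numeric(e[["0020,0032"]]),
                  numeric(3)))
  ord <- order(ipp[, 3L])
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]
  e1 <- slices[[1L]]
  nr <- dcm_us(e1[["0028,0010"]]); nc <- dcm_us(e1[["0028,0011"]])
  ps <- dcm_numeric(e1[["0028,0030"]])  # row, col spacing
  ns <- length(slices)
  dz <- if (ns > 1L) median(diff(ipp[, 3L])) else dcm_numeric(e1[["0018,0050"]])
  vox <- array(0, c(ns, nr, nc))
  for (k in seq_len(ns)) {
    e <- slices[[k]]
    slope <- if (!is.null(e[["0028,1053"]])) dcm_numeric(e[["0028,1053"]]) else 1
    inter <- if (!is.null(e[["0028,1052"]])) dcm_numeric(e[["0028,1052"]]) else 0
    pix <- readBin(e[["7FE0,0010"]]$value, "integer", n = nr * nc,
                   size = 2L, endian = "little")
    vox[k, , ] <- t(matrix(pix * slope + inter, nrow = nc))
  }
  image_volume(vox, spacing = c(dz, ps[1L], ps[2L]),
               origin = c(ipp[1L, 3L], ipp[1L, 2L], ipp[1L, 1L]))
}

# Read an RT-STRUCT and rasterize its contours on the grid of `vol`.
dcm_read_rtstruct <- function(path, vol) {
  el <- dcm_read_file(path)
  rois <- el[["3006,0020"]]$value
  contours <- el[["3006,0039"]]$value
  names_by_num <- list()
  for (it in rois) {
    num <- dcm_string(it[["3006,0022"]])
    names_by_num[[num]] <- dcm_string(it[["3006,0026"]])
  }
  structures <- list()
  for (it in contours) {
    num <- dcm_string(it[["3006,0084"]])
    nm <- names_by_num[[num]]
    if (is.null(nm)) stop("RT-STRUCT references unknown ROI number ", num)
    polys <- list()
    cs <- it[["3006,0040"]]
    if (!is.null(cs)) {
      for (ci in cs$value) {
        xyz <- dcm_numeric(ci[["3006,0050"]])
        m <- matrix(xyz, nrow = 3L)
        polys[[length(polys) + 1L]] <-
          list(x = m[1L, ], y = m[2L, ], z = m[3L, 1L])
      }
    }
    mask <- contours_to_mask(polys, dim(vol$voxels), vol$spacing, vol$origin)
    structures[[length(structures) + 1L]] <- named_structure(nm, mask)
  }
  structures
}
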