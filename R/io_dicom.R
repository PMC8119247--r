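# Minimal DICOM support for single-frame CT series, little-endian transfer
# syntaxes only (explicit "1.2.840.10008.1.2.1" and implicit
# "1.2.840.10008.1.2"). No R DICOM toolkit is part of this package's
# dependency set, so the subset of the format the pipeline needs is parsed
# and written directly: uncompressed 8/16-bit single-frame slices with
# axis-aligned orientations. DICOM patient coordinates are LPS (+x left,
# +y posterior, +z superior); the canonical frame used by ct_volume() is
# x right, y posterior, z superior, i.e. LPS with the first axis negated.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

# VRs that use the 4-byte length form in explicit encoding
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_uint16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

dcm_uint32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

enc_uint16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
enc_uint32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

pad_even <- function(value, pad = as.raw(0L)) {
  if (length(value) %% 2L == 1L) c(value, pad) else value
}

# Encode one data element in explicit VR little endian.
enc_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    value <- pad_even(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  header <- c(enc_uint16(group), enc_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(header, as.raw(c(0L, 0L)), enc_uint32(length(value)), value)
  } else {
    c(header, enc_uint16(length(value)), value)
  }
}

ds_string <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                               collapse = "\\")

#' Write a CT volume as a DICOM series
#'
#' Writes one uncompressed single-frame CT slice per axial plane (explicit
#' VR little endian, 16-bit signed pixels, rescale slope 1 / intercept
#' -1024), with spatial position and orientation tags describing the
#' canonical geometry. Primarily used to feed phantoms through the DICOM
#' reading path.
#'
#' @param volume A [ct_volume()].
#' @param directory Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_dicom_series <- function(volume, directory) {
  stopifnot_volume(volume)
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  d <- dim(volume$voxels)
  s <- volume$spacing
  o <- volume$origin
  study_uid <- "2.25.73001.1"
  series_uid <- "2.25.73001.2"
  intercept <- -1024
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- sprintf("2.25.73001.3.%d", k)
    # canonical voxel (1,1,k) centre in LPS
    ipp <- c(-o[1], o[2], o[3] + (k - 1) * s[3])
    # column index runs along canonical +x = LPS (-1,0,0); rows along +y
    iop <- c(-1, 0, 0, 0, 1, 0)
    raw_vals <- as.integer(round(volume$voxels[, , k]) - intercept)
    if (any(raw_vals < -32768L) || any(raw_vals > 32767L))
      stop("HU values out of range for 16-bit DICOM storage", call. = FALSE)
    pixel_bytes <- writeBin(raw_vals, raw(), size = 2L, endian = "little")
    dataset <- c(
      enc_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      enc_element(0x0008, 0x0018, "UI", sop_uid),
      enc_element(0x0008, 0x0060, "CS", "CT"),
      enc_element(0x0020, 0x000D, "UI", study_uid),
      enc_element(0x0020, 0x000E, "UI", series_uid),
      enc_element(0x0020, 0x0013, "IS", as.character(k)),
      enc_element(0x0020, 0x0032, "DS", ds_string(ipp)),
      enc_element(0x0020, 0x0037, "DS", ds_string(iop)),
      enc_element(0x0028, 0x0002, "US", enc_uint16(1L)),
      enc_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      enc_element(0x0028, 0x0010, "US", enc_uint16(d[2])),  # rows <-> y
      enc_element(0x0028, 0x0011, "US", enc_uint16(d[1])),  # cols <-> x
      enc_element(0x0028, 0x0030, "DS", ds_string(c(s[2], s[1]))),
      enc_element(0x0028, 0x0100, "US", enc_uint16(16L)),
      enc_element(0x0028, 0x0101, "US", enc_uint16(16L)),
      enc_element(0x0028, 0x0102, "US", enc_uint16(15L)),
      enc_element(0x0028, 0x0103, "US", enc_uint16(1L)),
      enc_element(0x0028, 0x1052, "DS", as.character(intercept)),
      enc_element(0x0028, 0x1053, "DS", "1"),
      enc_element(0x7FE0, 0x0010, "OW", pixel_bytes)
    )
    meta_body <- c(
      enc_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      enc_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      enc_element(0x0002, 0x0003, "UI", sop_uid),
      enc_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
      enc_element(0x0002, 0x0012, "UI", "2.25.73001.0.1")
    )
    meta <- c(enc_element(0x0002, 0x0000, "UL", enc_uint32(length(meta_body))),
              meta_body)
    path <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, dataset), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# Parse the data elements of one DICOM file into a named list of raw values
# for the tags the reader needs. `bytes` is the full file content.
parse_dicom_elements <- function(bytes, path) {
  n <- length(bytes)
  if (n < 140L || rawToChar(bytes[129:132]) != "DICM")
    return(NULL)
  p <- 133L
  wanted <- character(0)
  out <- list()
  explicit <- TRUE
  ts_uid <- NULL
  in_meta <- TRUE
  repeat {
    if (p + 7L > n) break
    group <- dcm_uint16(bytes, p)
    element <- dcm_uint16(bytes, p + 2L)
    if (in_meta && group != 0x0002L) {
      in_meta <- FALSE
      if (is.null(ts_uid))
        stop("missing TransferSyntaxUID (0002,0010) in ", path, call. = FALSE)
      if (ts_uid == UID_IMPLICIT_LE) explicit <- FALSE
      else if (ts_uid != UID_EXPLICIT_LE)
        stop("unsupported transfer syntax ", ts_uid, " in ", path,
             call. = FALSE)
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
      if (vr %in% LONG_VRS) {
        len <- dcm_uint32(bytes, p + 8L)
        val_at <- p + 12L
      } else {
        len <- dcm_uint16(bytes, p + 6L)
        val_at <- p + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_uint32(bytes, p + 4L)
      val_at <- p + 8L
    }
    if (len == 4294967295) # undefined length (sequences): not supported
      stop("undefined-length elements are not supported (", path, ")",
           call. = FALSE)
    key <- sprintf("%04X,%04X", group, element)
    if (in_meta && group == 0x0002L && element == 0x0010L)
      ts_uid <- raw_to_string(bytes[val_at:(val_at + len - 1L)])
    if (key %in% c("0020,0032", "0020,0037", "0028,0010", "0028,0011",
                   "0028,0030", "0028,0100", "0028,0103", "0028,1052",
                   "0028,1053", "7FE0,0010")) {
      out[[key]] <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    }
    p <- val_at + len
  }
  out
}

# DICOM UI values are NUL-padded to even length; drop the padding bytes
raw_to_string <- function(val) rawToChar(val[val != as.raw(0L)])

dcm_string <- function(val) {
  if (is.null(val)) return(NULL)
  trimws(raw_to_string(val))
}

dcm_numbers <- function(val) {
  s <- dcm_string(val)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

require_tag <- function(elems, key, what, path) {
  if (is.null(elems[[key]]))
    stop(sprintf("missing %s (%s) in %s", what, key, path), call. = FALSE)
  elems[[key]]
}

# Map an axis-aligned LPS direction vector onto (canonical axis, sign).
canonical_axis <- function(dir_lps) {
  dir_can <- c(-dir_lps[1], dir_lps[2], dir_lps[3])
  ax <- which.max(abs(dir_can))
  if (abs(abs(dir_can[ax]) - 1) > 1e-3 || sum(abs(dir_can[-ax])) > 1e-3)
    stop("oblique (non axis-aligned) orientations are not supported",
         call. = FALSE)
  list(axis = ax, sign = sign(dir_can[ax]))
}

#' Read a DICOM series as a CT volume
#'
#' Reads all single-frame CT slices in a directory (uncompressed explicit
#' or implicit VR little endian), converts stored values to Hounsfield
#' units via the modality rescale (`HU = raw * RescaleSlope +
#' RescaleIntercept`), sorts slices by spatial position along the slice
#' normal, and reorients into the canonical [ct_volume()] axes. Files
#' without a DICOM magic number are ignored.
#'
#' @param directory Directory containing one series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory))
    stop("DICOM directory not found: ", directory, call. = FALSE)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop("empty DICOM directory: ", directory, call. = FALSE)
  slices <- list()
  for (f in files) {
    bytes <- readBin(f, raw(), file.info(f)$size)
    elems <- parse_dicom_elements(bytes, f)
    if (is.null(elems) || is.null(elems[["7FE0,0010"]])) next
    rows <- dcm_uint16(require_tag(elems, "0028,0010", "Rows", f), 1L)
    cols <- dcm_uint16(require_tag(elems, "0028,0011", "Columns", f), 1L)
    bits <- dcm_uint16(require_tag(elems, "0028,0100", "BitsAllocated", f), 1L)
    if (!bits %in% c(8L, 16L))
      stop("unsupported BitsAllocated ", bits, " in ", f, call. = FALSE)
    signed <- !is.null(elems[["0028,0103"]]) &&
      dcm_uint16(elems[["0028,0103"]], 1L) == 1L
    slope <- dcm_numbers(require_tag(elems, "0028,1053", "RescaleSlope", f))[1]
    intercept <- dcm_numbers(
      require_tag(elems, "0028,1052", "RescaleIntercept", f))[1]
    ps <- dcm_numbers(require_tag(elems, "0028,0030", "PixelSpacing", f))
    ipp <- dcm_numbers(require_tag(elems, "0020,0032",
                                   "ImagePositionPatient", f))
    iop_el <- elems[["0020,0037"]]
    iop <- if (is.null(iop_el)) c(1, 0, 0, 0, 1, 0) else dcm_numbers(iop_el)
    pix <- elems[["7FE0,0010"]]
    expected <- rows * cols * (bits %/% 8L)
    if (length(pix) < expected)
      stop("truncated pixel data in ", f, call. = FALSE)
    vals <- readBin(pix, integer(), n = rows * cols, size = bits %/% 8L,
                    signed = signed, endian = "little")
    hu <- vals * slope + intercept
    slices[[length(slices) + 1L]] <- list(
      hu = matrix(hu, nrow = cols, ncol = rows),  # [col index, row index]
      rows = rows, cols = cols, ps = ps, ipp = ipp, iop = iop
    )
  }
  if (length(slices) < 2L)
    stop("need at least 2 readable DICOM slices in ", directory,
         call. = FALSE)
  rows0 <- slices[[1]]$rows; cols0 <- slices[[1]]$cols
  for (sl in slices)
    if (sl$rows != rows0 || sl$cols != cols0)
      stop("inconsistent in-plane dimensions across slices in ", directory,
           call. = FALSE)
  cdir <- slices[[1]]$iop[1:3]   # direction of increasing column index
  rdir <- slices[[1]]$iop[4:6]   # direction of increasing row index
  ndir <- c(cdir[2] * rdir[3] - cdir[3] * rdir[2],
            cdir[3] * rdir[1] - cdir[1] * rdir[3],
            cdir[1] * rdir[2] - cdir[2] * rdir[1])
  pos <- vapply(slices, function(sl) sum(sl$ipp * ndir), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  dz <- diff(pos)
  if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * stats::median(dz) + 1e-6)
    stop("slices are not uniformly spaced along the slice normal",
         call. = FALSE)
  arr <- array(0, c(cols0, rows0, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$hu
  src_spacing <- c(slices[[1]]$ps[2], slices[[1]]$ps[1], stats::median(dz))

  axes <- list(canonical_axis(cdir), canonical_axis(rdir),
               canonical_axis(ndir))
  tgt <- vapply(axes, `[[`, numeric(1), "axis")
  if (length(unique(tgt)) != 3L)
    stop("degenerate orientation: image axes are not independent",
         call. = FALSE)
  perm <- match(1:3, tgt)        # source axis feeding each canonical axis
  arr <- aperm(arr, perm)
  spacing <- src_spacing[perm]
  src_index <- c(1L, 1L, 1L)     # source voxel landing at canonical [1,1,1]
  for (ax in 1:3) {
    src <- perm[ax]
    if (axes[[src]]$sign < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- dim(arr)[ax]:1
      arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      src_index[src] <- dim(arr)[ax]
    }
  }
  steps <- c(slices[[1]]$ps[2], slices[[1]]$ps[1])
  origin_lps <- slices[[src_index[3]]]$ipp +
    (src_index[1] - 1) * steps[1] * cdir +
    (src_index[2] - 1) * steps[2] * rdir
  origin <- c(-origin_lps[1], origin_lps[2], origin_lps[3])
  ct_volume(arr, spacing = spacing, origin = origin)
}
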