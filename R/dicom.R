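# Minimal DICOM series reader: uncompressed, explicit-VR little-endian,
# single-frame axial CT slices. Only the tags needed for geometry and HU
# calibration are interpreted; everything else is skipped structurally.
# Scope is deliberately narrow — compressed transfer syntaxes, implicit VR
# and multi-frame objects are rejected with descriptive errors.

.dcm_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}

.dcm_u32 <- function(raw, off) {
  as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
}

# VRs that use the 2-byte-reserved + 4-byte-length layout
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one explicit-VR little-endian file into a named list of the tags we
# care about. `off` is a 0-based byte offset.
.dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  off <- 0L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") {
    off <- 132L
  }
  wanted <- c(
    "0002,0010", # TransferSyntaxUID
    "0008,0060", # Modality
    "0018,0050", # SliceThickness
    "0020,0013", # InstanceNumber
    "0020,0032", # ImagePositionPatient
    "0028,0010", # Rows
    "0028,0011", # Columns
    "0028,0030", # PixelSpacing
    "0028,0100", # BitsAllocated
    "0028,0103", # PixelRepresentation
    "0028,1052", # RescaleIntercept
    "0028,1053", # RescaleSlope
    "7fe0,0010"  # PixelData
  )
  out <- list()
  n <- length(raw)
  while (off + 8L <= n) {
    group <- .dcm_u16(raw, off)
    elem  <- .dcm_u16(raw, off + 2L)
    vr    <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported DICOM encoding in ", basename(path),
           " (only explicit-VR little-endian is supported)", call. = FALSE)
    }
    if (vr %in% .dcm_long_vrs) {
      len <- .dcm_u32(raw, off + 8L)
      hdr <- 12L
    } else {
      len <- .dcm_u16(raw, off + 6L)
      hdr <- 8L
    }
    if (!is.finite(len) || off + hdr + len > n) {
      stop("truncated DICOM element in ", basename(path), call. = FALSE)
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag %in% wanted) {
      body <- raw[(off + hdr + 1L):(off + hdr + len)]
      out[[tag]] <- if (tag == "7fe0,0010") body else
        trimws(rawToChar(body[body != as.raw(0)]))
      if (tag %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
        out[[tag]] <- .dcm_u16(raw, off + hdr)  # US binary
      }
    }
    off <- off + hdr + as.integer(len)
    if (tag == "7fe0,0010") break
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    stop("unsupported transfer syntax ", ts, " in ", basename(path),
         " (only explicit-VR little-endian, 1.2.840.10008.1.2.1)",
         call. = FALSE)
  }
  out
}

.dcm_ds <- function(x) as.numeric(strsplit(x, "\\\\")[[1]])

# Read one slice: returns list(instance, zpos, pixel_spacing, thickness,
# matrix [x, y] of HU values).
.dcm_read_slice <- function(path) {
  el <- .dcm_parse_file(path)
  modality <- el[["0008,0060"]]
  if (is.null(modality) || modality != "CT") {
    stop("not a CT slice (Modality=", if (is.null(modality)) "absent" else modality,
         "): ", basename(path), call. = FALSE)
  }
  need <- c("0020,0013", "0028,0010", "0028,0011", "0028,0030", "7fe0,0010")
  miss <- need[!need %in% names(el)]
  if (length(miss)) {
    stop("DICOM slice ", basename(path), " lacks required tag(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- el[["0028,0010"]]
  cols <- el[["0028,0011"]]
  bits <- el[["0028,0100"]]
  if (!is.null(bits) && bits != 16L) {
    stop("only 16-bit pixel data supported (BitsAllocated=", bits, ")",
         call. = FALSE)
  }
  signed <- identical(el[["0028,0103"]], 1L)
  px <- readBin(el[["7fe0,0010"]], "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  if (length(px) != rows * cols) {
    stop("pixel data length mismatch in ", basename(path), call. = FALSE)
  }
  slope <- if (is.null(el[["0028,1053"]])) 1 else as.numeric(el[["0028,1053"]])
  inter <- if (is.null(el[["0028,1052"]])) 0 else as.numeric(el[["0028,1052"]])
  ps <- .dcm_ds(el[["0028,0030"]])  # (row spacing = y, column spacing = x)
  ipp <- if (is.null(el[["0020,0032"]])) NULL else .dcm_ds(el[["0020,0032"]])
  list(
    instance = as.integer(as.numeric(el[["0020,0013"]])),
    zpos = if (is.null(ipp)) NA_real_ else ipp[3],
    spacing_xy = c(ps[2], ps[1]),
    thickness = if (is.null(el[["0018,0050"]])) NA_real_ else as.numeric(el[["0018,0050"]]),
    # DICOM pixels run column-fastest within a row: nrow = Columns gives [x, y]
    hu = matrix(px * slope + inter, nrow = cols, ncol = rows)
  )
}

#' Read a DICOM series directory as a CT volume
#'
#' Assembles all `.dcm` files (or all files, if none end in `.dcm`) in a
#' directory into a single [ct_volume()], ordered by InstanceNumber.
#' Rescale slope/intercept is applied per slice to recover Hounsfield units.
#' Missing instance numbers and inconsistent in-plane spacing raise
#' descriptive errors.
#'
#' @param dir Directory containing one axial CT series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, .dcm_read_slice)
  inst <- vapply(slices, `[[`, integer(1), "instance")
  ord <- order(inst)
  slices <- slices[ord]
  inst <- inst[ord]
  expected <- seq(min(inst), max(inst))
  gaps <- setdiff(expected, inst)
  if (length(gaps)) {
    stop("DICOM series has missing instance number(s): ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(inst)) {
    stop("DICOM series has duplicated instance numbers", call. = FALSE)
  }
  sxy <- t(vapply(slices, `[[`, numeric(2), "spacing_xy"))
  if (any(abs(sweep(sxy, 2L, sxy[1L, ])) > 1e-6)) {
    stop("inconsistent in-plane PixelSpacing across the series", call. = FALSE)
  }
  dims <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice dimensions across the series", call. = FALSE)
  }
  z <- vapply(slices, `[[`, numeric(1), "zpos")
  if (length(slices) > 1L && all(is.finite(z))) {
    dz <- diff(z)
    if (any(abs(dz - dz[1]) > 1e-4) || any(dz <= 0)) {
      stop("inconsistent slice z-positions (spacing varies or non-monotone)",
           call. = FALSE)
    }
    dz <- dz[1]
  } else {
    dz <- slices[[1]]$thickness
    if (!is.finite(dz)) dz <- 1
  }
  hu <- array(0, dim = c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) hu[, , k] <- slices[[k]]$hu
  ct_volume(hu, spacing = c(sxy[1, 1], sxy[1, 2], dz))
}
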