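# Tiny explicit-VR little-endian DICOM writer used to build fixture series
# in-memory at test time (no binary files are shipped).

.u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

.dcm_elem <- function(group, elem, vr, value) {
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    body <- value
    if (length(body) %% 2L) body <- c(body, as.raw(0))
    c(.u16le(group), .u16le(elem), charToRaw(vr), as.raw(c(0, 0)),
      .u32le(length(body)), body)
  } else if (vr == "US") {
    c(.u16le(group), .u16le(elem), charToRaw(vr), .u16le(2L), .u16le(value))
  } else {
    body <- charToRaw(as.character(value))
    if (length(body) %% 2L) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      body <- c(body, pad)
    }
    c(.u16le(group), .u16le(elem), charToRaw(vr), .u16le(length(body)), body)
  }
}

# pixels: integer matrix indexed [x (column), y (row)] of stored values
write_test_dicom <- function(path, pixels, instance, zpos = 0,
                             pixel_spacing = c(1, 1), thickness = 2.5,
                             slope = 1, intercept = -1024,
                             modality = "CT", signed = FALSE) {
  stored <- as.integer(t(pixels))  # row-by-row, column-fastest within a row
  px_raw <- writeBin(stored, raw(), size = 2L, endian = "little")
  out <- c(
    raw(128), charToRaw("DICM"),
    .dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dcm_elem(0x0008, 0x0060, "CS", modality),
    .dcm_elem(0x0018, 0x0050, "DS", format(thickness)),
    .dcm_elem(0x0020, 0x0013, "IS", as.character(instance)),
    .dcm_elem(0x0020, 0x0032, "DS",
              paste(0, 0, format(zpos), sep = "\\")),
    .dcm_elem(0x0028, 0x0010, "US", ncol(pixels)),  # Rows (y)
    .dcm_elem(0x0028, 0x0011, "US", nrow(pixels)),  # Columns (x)
    .dcm_elem(0x0028, 0x0030, "DS",
              paste(format(pixel_spacing[2]), format(pixel_spacing[1]), sep = "\\")),
    .dcm_elem(0x0028, 0x0100, "US", 16L),
    .dcm_elem(0x0028, 0x0103, "US", if (signed) 1L else 0L),
    .dcm_elem(0x0028, 0x1052, "DS", format(intercept)),
    .dcm_elem(0x0028, 0x1053, "DS", format(slope)),
    .dcm_elem(0x7fe0, 0x0010, "OW", px_raw)
  )
  writeBin(out, path)
  invisible(path)
}

# a small consistent series in a fresh temp directory
write_test_series <- function(n_slices = 3, nx = 4, ny = 3,
                              spacing = c(1, 1), dz = 2.5, base_value = 200,
                              instances = seq_len(n_slices)) {
  dir <- tempfile("dcm_series_")
  dir.create(dir)
  for (i in seq_along(instances)) {
    px <- matrix(base_value + instances[i], nrow = nx, ncol = ny)
    write_test_dicom(file.path(dir, sprintf("slice%02d.dcm", i)), px,
                     instance = instances[i], zpos = (instances[i] - 1) * dz,
                     pixel_spacing = spacing, thickness = dz)
  }
  dir
}
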