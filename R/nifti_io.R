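# NIfTI reading/writing (RNifti) and the volume/mask entry points.

#' Read a CT volume
#'
#' Reads a calibrated CT volume from NIfTI (`.nii` / `.nii.gz`) or from a
#' directory containing a DICOM series of axial slices. DICOM stored values
#' are converted to Hounsfield units with the per-file rescale slope and
#' intercept; slice ordering and z spacing are recovered from the image
#' positions.
#'
#' @param path File path (NIfTI) or directory (DICOM series).
#' @param format `"auto"` (default), `"nifti"`, or `"dicom"`.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom" else "nifti"
  }
  if (format == "nifti") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))  # drop NIfTI header attributes
    if (length(dim(arr)) != 3L) {
      stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dimensions",
           call. = FALSE)
    }
    ct_volume(arr, spacing = RNifti::pixdim(img)[1:3])
  } else {
    read_dicom_series(path)
  }
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel is treated as occupied.
#'
#' @param path NIfTI file path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D NIfTI mask", call. = FALSE)
  }
  binary_mask(array(arr != 0, dim = dim(arr)), spacing = RNifti::pixdim(img)[1:3])
}

#' Write a CT volume to NIfTI
#'
#' HU values are stored as 64-bit floats so the round trip through
#' [read_volume()] is lossless.
#'
#' @param ct A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(ct, path) {
  if (!inherits(ct, "ct_volume")) stop("`ct` must be a ct_volume", call. = FALSE)
  img <- RNifti::asNifti(ct$hu)
  RNifti::pixdim(img) <- ct$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a binary mask to NIfTI
#'
#' Occupancy is stored as 0/1 uint8.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask", call. = FALSE)
  img <- RNifti::asNifti(array(as.integer(mask$occupancy), dim = dim(mask$occupancy)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
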