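#' 3D scalar volume with voxel spacing
#'
#' Light-weight container for a 3D image: a numeric array plus per-axis
#' voxel spacing in millimetres.  Voxel indices are 1-based inside R (array
#' convention); all serialized coordinates (JSON ground truth, CSV candidate
#' tables) are 0-based, and millimetre coordinates place the centre of the
#' first voxel at the origin, so `mm = (index - 1) * spacing`.
#'
#' @param data numeric 3D array of intensities (arbitrary units).
#' @param spacing_mm numeric length-3, voxel size per axis in mm.
#' @param origin numeric length-3 world offset in mm.
#' @param case_id character scalar identifying the case.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0),
                     case_id = "case") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(data) == 0L) stop("volume grid is empty")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite values")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite")
  structure(
    list(data = data, spacing_mm = spacing_mm,
         origin = as.numeric(origin), case_id = as.character(case_id)),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d '%s'> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$case_id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Read a 3D volume from a NIfTI file
#'
#' Voxel spacing is taken from the NIfTI `pixdim` header.  Data are stored
#' (x, y, z) fastest-to-slowest, the NIfTI on-disk order.  4D files with a
#' singleton fourth dimension are accepted and dropped to 3D.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param case_id case identifier; defaults to the file name stem.
#' @return A [volume3d] object.
#' @export
read_volume <- function(path, case_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI file (", conditionMessage(e),
                         "): ", path, call. = FALSE))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { dim(arr) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), "D")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header field pixdim is missing or non-positive")
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume3d(arr, spacing_mm = sp, case_id = case_id)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param volume a [volume3d], or a 3D array/logical mask plus `spacing_mm`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing override when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing_mm = NULL) {
  if (inherits(volume, "volume3d")) {
    arr <- volume$data
    sp <- volume$spacing_mm
  } else {
    arr <- volume
    if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
    sp <- if (is.null(spacing_mm)) c(1, 1, 1) else spacing_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# mm coordinates of 1-based voxel indices (matrix or vector)
voxel_to_mm <- function(idx, spacing_mm) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sweep(idx - 1, 2, spacing_mm, `*`)
}
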