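#' @useDynLib bmseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif sd
#' @importFrom utils head read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Containers
#
# Axis convention (enforced at the I/O boundary): data arrays are ordered
# (slice z, row y, col x); spacing and origin are (dz, dy, dx) in mm.
# Indices are 0-based in all public coordinate arguments; patch windows are
# half-open [row, row + size).
# ---------------------------------------------------------------------------

#' Construct an image volume
#'
#' A 3D scalar grid with physical spacing and origin, used for MR images and
#' probability maps. Arrays are ordered (slice, row, col); spacing and origin
#' are (dz, dy, dx) in millimetres.
#'
#' @param data 3D numeric array, finite everywhere.
#' @param spacing numeric length-3, all positive, mm.
#' @param origin numeric length-3, mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("image_volume: `data` must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: `spacing` must be 3 positive finite values")
  if (any(!is.finite(data)))
    stop("image_volume: `data` contains non-finite values")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Construct a binary label volume
#'
#' A binary mask aligned to an [image_volume()]: ground-truth lesion
#' delineations or binarized predictions. Values must be 0/1.
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @inheritParams image_volume
#' @return An object of class `label_volume` (inherits `image_volume`).
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("label_volume: `data` must be a 3D array")
  d <- dim(data)
  storage.mode(data) <- "integer"
  if (!all(data == 0L | data == 1L))
    stop("label_volume: values must be 0 or 1")
  dim(data) <- d
  v <- image_volume(array(0, dim = d), spacing, origin)
  v$data <- data
  class(v) <- c("label_volume", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d (slice x row x col), spacing %.4g x %.4g x %.4g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s are on different grids (shape mismatch)", what))
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(sprintf("%s are on different grids (spacing mismatch)", what))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# NIfTI I/O
# ---------------------------------------------------------------------------

#' Read a volume from disk
#'
#' Reads a NIfTI file and returns it in the package's (slice, row, col) axis
#' order with spacing taken from the header. NIfTI stores data (x, y, z), so
#' axes are permuted on read and restored on write.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param format only `"nifti"` is supported; `"dicom_series"` raises an
#'   informative error (no DICOM reader is bundled).
#' @param label logical; if `TRUE` the result is validated and returned as a
#'   [label_volume()].
#' @return An `image_volume` or `label_volume`.
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series"),
                        label = FALSE) {
  format <- match.arg(format)
  if (format == "dicom_series")
    stop("read_volume: DICOM series input is not supported in this build; ",
         "convert the series to NIfTI first")
  if (!file.exists(path))
    stop("read_volume: cannot read '", path, "': no such file")
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)            # (dx, dy, dz)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("read_volume: '", path, "' is not a 3D volume")
  arr <- aperm(arr, c(3, 2, 1))        # (x,y,z) -> (z,y,x)
  spacing <- rev(pd[seq_len(3)])
  if (label) label_volume(arr, spacing) else image_volume(arr, spacing)
}

#' Write a volume to disk as NIfTI
#'
#' Label volumes are written as unsigned 8-bit, images as 32-bit float.
#'
#' @param v an `image_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "image_volume"))
  arr <- aperm(v$data, c(3, 2, 1))     # (z,y,x) -> (x,y,z)
  dt <- if (inherits(v, "label_volume")) "uint8" else "double"
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- rev(v$spacing)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling and physical volumes
# ---------------------------------------------------------------------------

#' Resample a volume to a target spacing
#'
#' The output grid extent along each axis is `round(n * spacing /
#' target_spacing)` (round-half-up on the physical extent), so e.g. a 3 mm
#' slice thickness resampled to 1 mm triples the slice count. Intensities are
#' interpolated trilinearly (`"linear"`, for images) or by nearest neighbour
#' (`"nearest"`, for label masks, which stay binary).
#'
#' @param v `image_volume` or `label_volume`.
#' @param target_spacing numeric length-3 (dz, dy, dx) in mm, all positive.
#' @param interpolation `"linear"` or `"nearest"`. Defaults to `"nearest"`
#'   for label volumes and `"linear"` otherwise.
#' @return A volume of the same class on the new grid.
#' @export
resample_volume <- function(v, target_spacing,
                            interpolation = if (inherits(v, "label_volume"))
                              "nearest" else "linear") {
  stopifnot(inherits(v, "image_volume"))
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("resample_volume: `target_spacing` must be 3 positive values")
  n <- dim(v$data)
  m <- pmax(1L, as.integer(floor(n * v$spacing / target_spacing + 0.5)))
  x <- v$data
  storage.mode(x) <- "double"
  out <- .cpp_resample3d(x, m, v$spacing, target_spacing,
                         interpolation == "nearest")
  if (inherits(v, "label_volume"))
    label_volume(out, target_spacing, v$origin)
  else
    image_volume(out, target_spacing, v$origin)
}

#' Physical volume of one voxel, in cc
#'
#' @param spacing numeric length-3 (dz, dy, dx) in mm.
#' @return dz * dy * dx / 1000, in cubic centimetres.
#' @export
voxel_volume_cc <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_volume_cc: spacing must be 3 positive values")
  prod(spacing) / 1000
}
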