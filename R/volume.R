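#' Image volume container
#'
#' A 3D scalar grid with physical voxel spacing. The axis order is fixed
#' package-wide as (slice, row, col), 0-based slice spacing along the first
#' axis. Physical volume of a voxel is `in_plane_mm^2 * slice_mm`.
#'
#' @param data 3D numeric array, dim = c(slices, rows, cols).
#' @param in_plane_mm In-plane voxel edge length in mm (isotropic in-plane).
#' @param slice_mm Distance between slices in mm.
#' @param is_mask Logical; if `TRUE`, values are restricted to {0, 1}.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, in_plane_mm, slice_mm, is_mask = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (slice, row, col)", call. = FALSE)
  if (!is.numeric(in_plane_mm) || in_plane_mm <= 0 ||
      !is.numeric(slice_mm) || slice_mm <= 0)
    stop("voxel spacings must be strictly positive", call. = FALSE)
  if (is_mask && !all(data %in% c(0, 1)))
    stop("mask volumes may contain only {0, 1}", call. = FALSE)
  structure(
    list(data = data, in_plane_mm = as.numeric(in_plane_mm),
         slice_mm = as.numeric(slice_mm), is_mask = isTRUE(is_mask)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d (slice,row,col), %.3g x %.3g mm in-plane, %.3g mm slices%s\n",
              d[1], d[2], d[3], x$in_plane_mm, x$in_plane_mm, x$slice_mm,
              if (x$is_mask) ", mask" else ""))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

voxel_volume_mm3 <- function(vol) vol$in_plane_mm^2 * vol$slice_mm

stopifnot_same_grid <- function(..., what = "volumes") {
  vols <- list(...)
  d <- dim(vols[[1]]$data)
  for (v in vols[-1]) {
    if (!identical(dim(v$data), d) ||
        abs(v$in_plane_mm - vols[[1]]$in_plane_mm) > 1e-6 ||
        abs(v$slice_mm - vols[[1]]$slice_mm) > 1e-6)
      stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI file as an image volume
#'
#' The NIfTI (x, y, z) axes are mapped onto the package's (slice, row, col)
#' convention: z becomes the slice axis. In-plane spacing must be (near)
#' isotropic; anisotropy beyond 1% triggers a warning and the mean is used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param is_mask Interpret the volume as a binary mask.
#' @return An `image_volume`.
#' @export
read_volume <- function(path, is_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  if (abs(pix[1] - pix[2]) > 0.01 * mean(pix[1:2]))
    warning("anisotropic in-plane spacing in ", path, "; using the mean")
  data <- aperm(arr, c(3, 2, 1))
  if (is_mask) data <- (data > 0.5) * 1
  image_volume(data, in_plane_mm = mean(pix[1:2]), slice_mm = pix[3], is_mask = is_mask)
}

#' Write an image volume to NIfTI
#'
#' Inverse of [read_volume()]: round-trips data (bit-exact for masks, to float
#' precision for intensities) and spacing.
#'
#' @param vol An `image_volume`.
#' @param path Output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  arr <- aperm(vol$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$in_plane_mm, vol$in_plane_mm, vol$slice_mm)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = if (vol$is_mask) "uint8" else "double")
  invisible(path)
}
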