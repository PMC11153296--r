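#' Voxel image container
#'
#' A minimal 3-D scalar image: a numeric array plus isotropic-or-not voxel
#' size in mm (RAS+ axis order is assumed throughout the package; phantom
#' generation and NIfTI round-trips both use it).
#'
#' @param data 3-D numeric array.
#' @param vox_mm voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, vox_mm) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array", call. = FALSE)
  if (length(vox_mm) == 1L) vox_mm <- rep(vox_mm, 3L)
  if (length(vox_mm) != 3L || any(vox_mm <= 0)) {
    stop("'vox_mm' must be 1 or 3 positive values", call. = FALSE)
  }
  structure(list(data = data, vox_mm = as.numeric(vox_mm)), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf(
    "<voxel_image %s @ %s mm, range [%g, %g]>\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$vox_mm, 3), collapse = "x"),
    min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

# internal: volume of one voxel in ml (1 ml = 1000 mm^3)
voxel_volume_ml <- function(img) prod(img$vox_mm) / 1000

# internal: stop unless two images share grid and voxel size
check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$vox_mm - b$vox_mm)) > 1e-9) {
    stop("voxel grids are not aligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a voxel image as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}; voxel size is stored in the header
#' pixdim and restored on read.
#'
#' @param img a [voxel_image()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_voxel_image` returns a [voxel_image()];
#'   `write_voxel_image` returns `path` invisibly.
#' @export
write_voxel_image <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$vox_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  nii <- RNifti::readNifti(path)
  voxel_image(array(as.numeric(nii), dim = dim(nii)), RNifti::pixdim(nii)[1:3])
}
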