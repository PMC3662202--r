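#' 3D scalar volume with voxel spacing
#'
#' A light container for a 3D image grid: a numeric array plus the voxel
#' size in millimetres per axis. Axial slices are indexed along the third
#' axis; voxel indices are reported 1-based (R convention) throughout.
#'
#' @param data numeric 3D array.
#' @param voxel_size numeric length-3, mm per axis (a scalar is recycled).
#' @return An object of class `vm_volume`.
#' @export
vm_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    vm_stop("parameter", "data must be a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    vm_stop("parameter", "voxel_size must be 3 positive numbers (mm)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "vm_volume")
}

#' @export
print.vm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vm_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
plot.vm_volume <- function(x, slice = NULL, ...) {
  slice <- slice %||% which.max(apply(x$data, 3, sum))
  graphics::image(x$data[, , slice], col = grDevices::gray.colors(128),
                  asp = dim(x$data)[2] / dim(x$data)[1], axes = FALSE,
                  main = sprintf("axial slice %d", slice), ...)
  invisible(x)
}

voxel_volume_mm3 <- function(x) prod(x$voxel_size)

#' Binary ventricle mask
#'
#' Voxel value 1 marks a ventricle voxel, 0 anything else. `provenance`
#' records the thresholds and morphology parameters that produced the mask.
#'
#' @param mask logical or 0/1 3D array.
#' @param voxel_size mm per axis.
#' @param provenance named list of extraction parameters.
#' @return An object of class `vm_mask`.
#' @export
vm_mask <- function(mask, voxel_size = c(1, 1, 1), provenance = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    vm_stop("parameter", "mask must be a 3D array")
  m <- mask != 0
  if (anyNA(m)) vm_stop("parameter", "mask contains NA")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(mask = array(as.integer(m), dim(mask)),
                 voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "vm_mask")
}

#' @export
print.vm_mask <- function(x, ...) {
  cat(sprintf("<vm_mask> %s voxels set of %s (%.1f mm^3)\n",
              format(sum(x$mask)), format(length(x$mask)),
              sum(x$mask) * prod(x$voxel_size)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [vm_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) vm_stop("io", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    vm_stop("io", "expected a 3D NIfTI volume: %s", path)
  arr <- array(as.numeric(img), dim(img))  # plain array, NIfTI header dropped
  vm_volume(arr, voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as unsigned 8-bit integers, images as 32-bit floats.
#'
#' @param x a [vm_volume] or [vm_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "vm_mask")) {
    arr <- x$mask
    dt <- "uint8"
  } else if (inherits(x, "vm_volume")) {
    arr <- x$data
    dt <- "float"
  } else vm_stop("parameter", "x must be a vm_volume or vm_mask")
  attr(arr, "pixdim") <- x$voxel_size
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) write_volume(x, path)

#' Dice overlap between two binary masks
#'
#' @param a,b [vm_mask] objects or 0/1 arrays on the same grid.
#' @return Dice coefficient in `[0, 1]` (1 for two empty masks).
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "vm_mask")) a$mask else a != 0
  mb <- if (inherits(b, "vm_mask")) b$mask else b != 0
  if (!identical(dim(ma), dim(mb))) vm_stop("grid", "mask grids differ")
  s <- sum(ma) + sum(mb)
  if (s == 0) return(1)
  2 * sum(ma & mb) / s
}
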