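#' Group probability map from binary ventricle masks
#'
#' The voxelwise mean of N binary masks: each value is the fraction of
#' training subjects whose ventricle covers that voxel, so values lie on
#' the grid 0, 1/N, ..., 1.
#'
#' @param masks list of [vm_mask] objects on the same grid.
#' @param group the group the masks come from (`"NC"`, `"MCI"`, `"AD"`).
#' @return An object of class `vm_probmap` with `values`, `group`, `n_train`.
#' @export
build_probability_map <- function(masks, group = NA_character_) {
  if (length(masks) < 1L) vm_stop("parameter", "need at least one mask")
  arrs <- lapply(masks, function(m) {
    if (inherits(m, "vm_mask")) m$mask else array(as.integer(m != 0), dim(m))
  })
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d))
    vm_stop("grid", "all masks must share the same grid")
  structure(list(values = Reduce(`+`, arrs) / length(arrs),
                 group = group, n_train = length(arrs)),
            class = "vm_probmap")
}

#' Discriminate map: patient minus normal probability map
#'
#' Voxelwise difference `P_patient - P_normal`; positive where the patient
#' group's ventricles occupy space the controls' do not. Antisymmetric
#' under swapping its arguments.
#'
#' @param p_patient,p_normal [build_probability_map] results on one grid.
#' @return An object of class `vm_dmap` with `values` in `[-1, 1]` and the
#'   `contrast` (patient group, normal group).
#' @export
discriminate_map <- function(p_patient, p_normal) {
  if (!inherits(p_patient, "vm_probmap") || !inherits(p_normal, "vm_probmap"))
    vm_stop("parameter", "arguments must come from build_probability_map()")
  if (!identical(dim(p_patient$values), dim(p_normal$values)))
    vm_stop("grid", "probability maps are on different grids")
  structure(list(values = p_patient$values - p_normal$values,
                 contrast = c(p_patient$group, p_normal$group)),
            class = "vm_dmap")
}

#' Matching coefficient of a test mask against a discriminate map
#'
#' The inner product over all voxels of the discriminate map with the test
#' subject's binary ventricle mask, the 3D shape score used to compare a
#' held-out subject with group templates built without it.
#'
#' @param dmap a [discriminate_map] result.
#' @param test_mask a [vm_mask] on the same grid.
#' @return A scalar matching coefficient.
#' @export
matching_coefficient <- function(dmap, test_mask) {
  if (!inherits(dmap, "vm_dmap"))
    vm_stop("parameter", "dmap must come from discriminate_map()")
  m <- if (inherits(test_mask, "vm_mask")) test_mask$mask else test_mask
  if (!identical(dim(dmap$values), dim(m)))
    vm_stop("grid", "mask grid does not match the discriminate map")
  sum(dmap$values * (m != 0))
}

#' Write a probability or discriminate map as float NIfTI
#'
#' @param map a `vm_probmap` or `vm_dmap`.
#' @param path output path.
#' @param voxel_size mm per axis.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size = c(1, 1, 1)) {
  if (!inherits(map, c("vm_probmap", "vm_dmap")))
    vm_stop("parameter", "map must be a vm_probmap or vm_dmap")
  vals <- map$values
  attr(vals, "pixdim") <- voxel_size
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "float"), path)
  invisible(path)
}
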