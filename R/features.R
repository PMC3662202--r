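#' Canonical feature column names
#'
#' The default volume feature set holds the three tissue volumes; the
#' whole-brain and ventricular volumes are computed and stored alongside
#' but are not part of the default classification set. The shape set holds
#' the 17 datum-slice descriptors.
#'
#' @return Character vector of column names.
#' @export
volume_feature_names <- function() c("V_GM", "V_WM", "V_CSF")

#' @rdname volume_feature_names
#' @export
shape_feature_names <- function() shape2d_names

#' Segment one subject and compute its feature vector
#'
#' Runs the full single-subject chain: Gaussian-mixture tissue
#' segmentation, voxel-count volumetry, double-threshold region-growing
#' ventricle extraction, datum-slice selection and the 17 2D shape
#' descriptors.
#'
#' @param image a [vm_volume].
#' @param gmm_seed seed passed to [fit_tissue_gmm].
#' @param ... further arguments to [extract_ventricle].
#' @return A list of class `vm_subject`: `features` (named numeric vector
#'   with `V_GM`, `V_WM`, `V_CSF`, `V_Whole`, `V_Ventricle` and the shape
#'   columns), `maps`, `mask`, `datum` (slice index).
#' @export
extract_features <- function(image, gmm_seed = 1L, ...) {
  maps <- fit_tissue_gmm(image, seed = gmm_seed)
  mask <- extract_ventricle(image, maps, ...)
  dz <- datum_slice(mask)
  if (image$voxel_size[1] != image$voxel_size[2])
    vm_stop("parameter", "datum-slice descriptors need in-plane isotropic voxels")
  sh <- shape2d(mask$mask[, , dz], pixel_size = image$voxel_size[1])
  feats <- c(V_GM = tissue_volume(maps, "GM"),
             V_WM = tissue_volume(maps, "WM"),
             V_CSF = tissue_volume(maps, "CSF"),
             V_Whole = tissue_volume(maps, "whole"),
             V_Ventricle = ventricle_volume(mask),
             as_feature_row(sh))
  structure(list(features = feats, maps = maps, mask = mask, datum = dz),
            class = "vm_subject")
}

#' Feature table for a whole cohort
#'
#' @param cohort a [generate_cohort] result.
#' @param gmm_seed seed for the per-subject mixture fits.
#' @return A list with `table` (data frame: `subject_id`, `group` and all
#'   feature columns) and `masks` (per-subject [vm_mask] list, for the
#'   matching-coefficient features).
#' @export
cohort_features <- function(cohort, gmm_seed = 1L) {
  if (!inherits(cohort, "vm_cohort"))
    vm_stop("parameter", "cohort must come from generate_cohort()")
  n <- length(cohort$subjects)
  rows <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- extract_features(cohort$subjects[[i]]$image, gmm_seed = gmm_seed)
    rows[[i]] <- sub$features
    masks[[i]] <- sub$mask
  }
  tab <- cbind(cohort$manifest[, c("subject_id", "group")],
               as.data.frame(do.call(rbind, rows)))
  list(table = tab, masks = masks)
}
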