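# 3D morphology with the 6-connected radius-1 structuring element
# (face-neighbour cross). Outside the grid counts as background.

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

neigh6 <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

erode6 <- function(m) {
  out <- m
  for (s in neigh6) out <- out & shift3(m, s[1], s[2], s[3])
  out
}

dilate6 <- function(m) {
  out <- m
  for (s in neigh6) out <- out | shift3(m, s[1], s[2], s[3])
  out
}

open6 <- function(m) dilate6(erode6(m))
close6 <- function(m) erode6(dilate6(m))

# Default seed region: the largest interior high-CSF component (p_csf >
# 0.5 eroded by one voxel), which excludes the thin peripheral CSF shell
# and spans the whole cavity. Returns its linear voxel indices.
default_ventricle_seeds <- function(maps) {
  core <- erode6(maps$p_csf > 0.5)
  if (!any(core)) vm_stop("segmentation",
                          "no interior CSF region to seed ventricle growth")
  lab <- .label_components6(as.logical(core), dim(core))
  largest <- which.max(tabulate(lab[lab > 0]))
  which(lab == largest)
}

#' Extract the ventricles by double-threshold region growing
#'
#' Grows a 6-connected region from the seed voxel(s), accepting voxels
#' whose intensity lies in the band `[t_low, t_high]` (by default the
#' fitted CSF class mean +/- 2 CSF s.d.), then applies a morphological
#' opening followed by a closing (6-connected radius-1 element) and keeps
#' the connected component(s) containing the seed(s). By default the seed
#' region is the largest interior high-CSF component (`p_csf > 0.5` eroded
#' by one voxel), which spans the whole cavity while excluding the thin
#' peripheral CSF; seeding from the full region keeps both lateral lobes
#' when noise or morphology disconnects them.
#'
#' @param image a [vm_volume].
#' @param maps the [fit_tissue_gmm] result for `image` (used for default
#'   thresholds and the default seed region).
#' @param t_low,t_high intensity thresholds; defaults from the CSF class.
#' @param seed_point optional seed override: an integer length-3 voxel
#'   index (1-based), or a matrix of such rows.
#' @param morphology apply opening + closing (default TRUE).
#' @return A [vm_mask] whose `provenance` records thresholds and seeds.
#' @export
extract_ventricle <- function(image, maps, t_low = NULL, t_high = NULL,
                              seed_point = NULL, morphology = TRUE) {
  if (!inherits(image, "vm_volume"))
    vm_stop("parameter", "image must be a vm_volume")
  if (!inherits(maps, "vm_tissue_maps"))
    vm_stop("parameter", "maps must come from fit_tissue_gmm()")
  csf_sd <- sqrt(maps$variances[["CSF"]])
  t_low <- t_low %||% (maps$means[["CSF"]] - 2 * csf_sd)
  t_high <- t_high %||% (maps$means[["CSF"]] + 2 * csf_sd)
  if (t_low > t_high) vm_stop("parameter", "t_low must be <= t_high")
  d <- dim(image$data)
  if (is.null(seed_point)) {
    seed_lin <- default_ventricle_seeds(maps)
  } else {
    pts <- if (is.matrix(seed_point)) seed_point else matrix(seed_point, 1)
    if (ncol(pts) != 3L || any(pts < 1L) ||
        any(pts > matrix(d, nrow(pts), 3, byrow = TRUE)))
      vm_stop("parameter", "seed_point must be voxel indices inside the grid")
    seed_lin <- pts[, 1] + d[1] * (pts[, 2] - 1) + d[1] * d[2] * (pts[, 3] - 1)
  }
  band <- image$data >= t_low & image$data <= t_high & maps$mask
  if (!any(band[seed_lin]))
    vm_stop("empty_mask",
            "no voxel within the threshold band [%g, %g] at the seed point(s)",
            t_low, t_high)
  grown <- array(.flood_fill6(as.logical(band), d, as.integer(seed_lin)), d)
  m <- grown
  if (morphology) m <- close6(open6(m))
  if (any(m)) {
    lab <- .label_components6(as.logical(m), d)
    keep <- setdiff(unique(lab[seed_lin]), 0L)
    if (length(keep) == 0L) {
      # morphology removed every seed voxel: keep the component with the
      # largest overlap with the grown region
      overlaps <- tabulate(lab[as.vector(grown) & lab > 0], nbins = max(lab))
      keep <- which.max(overlaps)
    }
    m <- array(lab %in% keep, d)
  }
  if (!any(m)) vm_stop("empty_mask", "ventricle mask is empty after morphology")
  vm_mask(m, image$voxel_size,
          provenance = list(t_low = t_low, t_high = t_high,
                            n_seeds = length(seed_lin),
                            morphology = morphology,
                            connectivity = 6L, struct_radius = 1L))
}

#' Slice-wise Sobel boundary of a binary mask
#'
#' Applies the 3x3 Sobel operator to every axial slice of the binary mask
#' (zero padding at slice borders) and marks the mask pixels with nonzero
#' gradient magnitude: the one-pixel boundary ring of the ventricle on
#' each slice. Interior pixels have zero gradient and are never marked.
#'
#' @param mask a [vm_mask].
#' @return A [vm_mask] of boundary pixels.
#' @export
ventricle_edges <- function(mask) {
  if (!inherits(mask, "vm_mask")) vm_stop("parameter", "mask must be a vm_mask")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)         # d/dx
  ky <- t(kx)                                                 # d/dy
  d <- dim(mask$mask)
  out <- array(0L, d)
  for (z in seq_len(d[3])) {
    sl <- mask$mask[, , z]
    if (!any(sl != 0)) next
    pad <- matrix(0, d[1] + 2, d[2] + 2)
    pad[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
    gx <- matrix(0, d[1], d[2]); gy <- gx
    for (i in 1:3) for (j in 1:3) {
      blk <- pad[i:(i + d[1] - 1), j:(j + d[2] - 1)]
      gx <- gx + kx[i, j] * blk
      gy <- gy + ky[i, j] * blk
    }
    out[, , z] <- as.integer((gx != 0 | gy != 0) & sl != 0)
  }
  vm_mask(out, mask$voxel_size, provenance = list(op = "sobel_slicewise"))
}

#' Ventricular volume of a binary mask
#'
#' Counts mask voxels equal to 1 and multiplies by the voxel volume.
#'
#' @param mask a [vm_mask].
#' @return Volume in mm^3.
#' @export
ventricle_volume <- function(mask) {
  if (!inherits(mask, "vm_mask")) vm_stop("parameter", "mask must be a vm_mask")
  sum(mask$mask) * prod(mask$voxel_size)
}
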