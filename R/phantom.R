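#' Specification of a synthetic brain phantom
#'
#' Parameters of one seeded phantom: a T1-like ellipsoidal "brain" with a
#' white-matter core, a concentric gray-matter shell, a thin peripheral CSF
#' shell, and a central CSF-filled ventricular cavity shaped as two mirrored
#' teardrop lobes joined at the midline. Intensity order is CSF < GM < WM
#' and the background is exactly 0 (no skull is modelled). `ventricle_scale`
#' multiplies the cavity volume and simultaneously drives cortical atrophy
#' (thinner GM, smaller WM core, thicker peripheral CSF), so enlarged
#' ventricles co-occur with tissue loss as in degenerative disease.
#' `horn_asymmetry` lengthens the frontal horns relative to the posterior
#' bodies.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 16).
#' @param voxel_size mm per axis.
#' @param group one of `"NC"`, `"MCI"`, `"AD"`.
#' @param gm_mean,wm_mean,csf_mean class intensities (arbitrary units).
#' @param noise_sd Gaussian intensity noise s.d. (>= 0), added inside the
#'   brain only.
#' @param ventricle_scale dimensionless cavity volume multiplier (>= 0).
#' @param horn_asymmetry dimensionless frontal-horn length modulation.
#' @param seed integer seed; a fixed seed gives bit-identical phantoms.
#' @return An object of class `vm_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 72, 40),
                         voxel_size = c(2.5, 2.5, 2.5),
                         group = c("NC", "MCI", "AD"),
                         gm_mean = 110, wm_mean = 170, csf_mean = 40,
                         noise_sd = 8,
                         ventricle_scale = 1,
                         horn_asymmetry = 1,
                         seed = 1L) {
  group <- match.arg(group)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || anyNA(grid_shape) || any(grid_shape < 16L))
    vm_stop("parameter", "grid_shape must be 3 integers, each >= 16")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) vm_stop("parameter", "voxel_size must be positive")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(ventricle_scale, "ventricle_scale", min = 0)
  check_number(horn_asymmetry, "horn_asymmetry", min = 0, strict = TRUE)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 group = group, gm_mean = gm_mean, wm_mean = wm_mean,
                 csf_mean = csf_mean, noise_sd = noise_sd,
                 ventricle_scale = ventricle_scale,
                 horn_asymmetry = horn_asymmetry, seed = as.integer(seed)),
            class = "vm_phantom_spec")
}

phantom_classes <- c("background", "GM", "WM", "CSF", "ventricle")

# Integer label array for a spec: 0 background, 1 GM, 2 WM, 3 CSF, 4 ventricle.
phantom_labels <- function(spec) {
  d <- spec$grid_shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  ax <- 0.44 * d[1]; ay <- 0.46 * d[2]; az <- 0.42 * d[3]
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d) - cx
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d) - cy
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d) - cz
  r <- sqrt((X / ax)^2 + (Y / ay)^2 + (Z / az)^2)

  t <- spec$ventricle_scale
  csf_frac <- 0.05 + 0.06 * (t - 1)          # peripheral CSF thickens
  s_wm <- 0.68 - 0.04 * (t - 1)              # WM core shrinks
  s_gm <- 1 - csf_frac                       # GM shell thins
  lab <- array(0L, d)
  lab[r <= 1] <- 3L                          # peripheral CSF
  lab[r <= s_gm] <- 1L                       # GM shell
  lab[r <= s_wm] <- 2L                       # WM core

  # Ventricular cavity: two mirrored teardrop lobes (posterior body is a
  # wide half-ellipsoid, frontal horn a narrow longer one) plus a thin
  # midline bridge so the cavity is one 6-connected component. Anterior is
  # low y, posterior high y; linear dimensions scale as volume^(1/3).
  q <- t^(1 / 3)
  x0 <- 0.09 * d[1] * q
  wx_p <- 0.085 * d[1] * q; wz_p <- 0.11 * d[3] * q; ly_p <- 0.16 * d[2] * q
  wx_f <- 0.055 * d[1] * q; wz_f <- 0.08 * d[3] * q
  ly_f <- 0.20 * d[2] * q * spec$horn_asymmetry
  vent <- array(FALSE, d)
  for (s in c(-1, 1)) {
    XL <- X - s * x0
    post <- Y >= 0 & (XL / wx_p)^2 + (Y / ly_p)^2 + (Z / wz_p)^2 <= 1
    front <- Y < 0 & (XL / wx_f)^2 + (Y / ly_f)^2 + (Z / wz_f)^2 <= 1
    vent <- vent | post | front
  }
  bridge <- abs(X) <= x0 & abs(Y) <= 0.25 * ly_p & abs(Z) <= 0.5 * wz_p
  vent <- vent | bridge
  vent <- vent & lab == 2L                   # cavity carved out of the WM core
  lab[vent] <- 4L
  lab
}

#' Generate one synthetic brain phantom
#'
#' @param spec a [phantom_spec].
#' @return A list of class `vm_phantom` with elements `image` (a
#'   [vm_volume]), and `truth` (class `vm_phantom_truth`: the integer
#'   `label_volume` with levels background/GM/WM/CSF/ventricle, the
#'   `true_volumes` in mm^3 per class, and the `group` label).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 7))
#' ph$truth$true_volumes
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "vm_phantom_spec"))
    vm_stop("parameter", "spec must come from phantom_spec()")
  lab <- phantom_labels(spec)
  means <- c(0, spec$gm_mean, spec$wm_mean, spec$csf_mean, spec$csf_mean)
  img <- array(means[lab + 1L], dim(lab))
  if (spec$noise_sd > 0) {
    idx <- which(lab != 0L)
    img[idx] <- img[idx] +
      with_seed(spec$seed, rnorm(length(idx), 0, spec$noise_sd))
  }
  vv <- prod(spec$voxel_size)
  counts <- tabulate(lab + 1L, nbins = 5L)
  truth <- structure(list(label_volume = lab,
                          true_volumes = stats::setNames(counts * vv,
                                                         phantom_classes),
                          group = spec$group),
                     class = "vm_phantom_truth")
  structure(list(image = vm_volume(img, spec$voxel_size), truth = truth,
                 spec = spec),
            class = "vm_phantom")
}

#' @export
print.vm_phantom <- function(x, ...) {
  cat(sprintf("<vm_phantom> group %s, seed %d\n", x$spec$group, x$spec$seed))
  print(round(x$truth$true_volumes))
  invisible(x)
}

#' Group presets for cohort generation
#'
#' Default per-group overrides: the ventricular cavity grows and the frontal
#' horns lengthen from NC through MCI to AD, which (via the atrophy coupling
#' in [phantom_spec]) also shrinks GM/WM and thickens peripheral CSF in the
#' same direction. `jitter_sd` is the s.d. of the per-subject lognormal
#' jitter applied to `ventricle_scale` (and, halved, to `horn_asymmetry`).
#'
#' @param ventricle_scale named per-group cavity multipliers (NC < MCI < AD).
#' @param horn_asymmetry named per-group frontal-horn modulation.
#' @param jitter_sd per-subject lognormal jitter s.d.
#' @return A list of class `vm_cohort_presets`.
#' @export
cohort_presets <- function(ventricle_scale = c(NC = 1.0, MCI = 1.25, AD = 1.5),
                           horn_asymmetry = c(NC = 1.0, MCI = 1.1, AD = 1.2),
                           jitter_sd = 0.05) {
  if (!(ventricle_scale["NC"] < ventricle_scale["MCI"] &&
        ventricle_scale["MCI"] < ventricle_scale["AD"]))
    vm_stop("parameter",
            "preset ventricle_scale must be strictly ordered NC < MCI < AD")
  structure(list(ventricle_scale = ventricle_scale,
                 horn_asymmetry = horn_asymmetry, jitter_sd = jitter_sd),
            class = "vm_cohort_presets")
}

#' Generate a seeded phantom cohort
#'
#' Per-subject seeds and jitters are derived deterministically from the
#' master seed, so the same call reproduces the same cohort bit for bit.
#'
#' @param n_per_group subjects per group: a single integer or a named
#'   vector over NC/MCI/AD. The default reproduces a 17/18/17 cohort.
#' @param presets a [cohort_presets].
#' @param seed master seed.
#' @param ... further arguments passed to [phantom_spec] (grid, intensities,
#'   noise).
#' @return A list of class `vm_cohort`: one [generate_phantom] result per
#'   subject plus a `manifest` data frame (subject_id, group, seed).
#' @export
generate_cohort <- function(n_per_group = c(NC = 17, MCI = 18, AD = 17),
                            presets = cohort_presets(), seed = 1L, ...) {
  groups <- c("NC", "MCI", "AD")
  if (length(n_per_group) == 1L)
    n_per_group <- stats::setNames(rep(n_per_group, 3L), groups)
  n_per_group <- n_per_group[groups]
  if (anyNA(n_per_group) || any(n_per_group < 2))
    vm_stop("parameter",
            "n_per_group must give >= 2 subjects for each of NC, MCI, AD")
  n <- sum(n_per_group)
  seeds <- derive_seeds(seed, n)
  jit <- with_seed(seed + 1L, rnorm(2L * n, 0, presets$jitter_sd))
  group <- rep(groups, times = n_per_group)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    g <- group[i]
    subjects[[i]] <- generate_phantom(phantom_spec(
      group = g,
      ventricle_scale = presets$ventricle_scale[[g]] * exp(jit[2 * i - 1]),
      horn_asymmetry = presets$horn_asymmetry[[g]] * exp(jit[2 * i] / 2),
      seed = seeds[i], ...))
  }
  manifest <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, seed = seeds, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest, seed = seed),
            class = "vm_cohort")
}

#' @export
print.vm_cohort <- function(x, ...) {
  cat(sprintf("<vm_cohort> %d subjects (%s)\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk as NIfTI plus a manifest CSV
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if needed).
#' @return The manifest data frame (with file paths), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$image_path <- file.path(dir, paste0(man$subject_id, ".nii.gz"))
  man$label_path <- file.path(dir, paste0(man$subject_id, "_labels.nii.gz"))
  for (i in seq_len(nrow(man))) {
    s <- cohort$subjects[[i]]
    write_volume(s$image, man$image_path[i])
    lab <- s$truth$label_volume
    attr(lab, "pixdim") <- s$image$voxel_size
    RNifti::writeNifti(RNifti::asNifti(lab, datatype = "uint8"),
                       man$label_path[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
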