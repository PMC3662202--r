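test_that("the mixture fit on a noise-free phantom recovers 0/1 posteriors
          and the exact class counts", {
  ph <- test_phantom(seed = 1, noise_sd = 0)
  maps <- fit_tissue_gmm(ph$image)
  lab <- ph$truth$label_volume
  expect_true(all(maps$p_gm[lab == 1L] > 1 - 1e-9))
  expect_true(all(maps$p_wm[lab == 2L] > 1 - 1e-9))
  expect_true(all(maps$p_csf[lab %in% c(3L, 4L)] > 1 - 1e-9))
  vv <- prod(ph$image$voxel_size)
  expect_equal(tissue_volume(maps, "GM"), sum(lab == 1L) * vv)
  expect_equal(tissue_volume(maps, "WM"), sum(lab == 2L) * vv)
  expect_equal(tissue_volume(maps, "CSF"), sum(lab %in% c(3L, 4L)) * vv)
  expect_equal(tissue_volume(maps, "whole"), sum(lab %in% c(1L, 2L)) * vv)
})

test_that("EM log-likelihood is nondecreasing and posteriors sum to one", {
  ph <- test_phantom(seed = 2)
  maps <- fit_tissue_gmm(ph$image)
  expect_true(all(diff(maps$loglik) > -1e-8))
  tot <- maps$p_gm + maps$p_wm + maps$p_csf
  expect_true(all(abs(tot[maps$mask] - 1) < 1e-9))
  expect_true(all(tot[!maps$mask] == 0))
  expect_true(all(maps$variances > 0))
})

test_that("permuted initial class order yields identical mean-sorted maps", {
  ph <- test_phantom(seed = 3)
  m1 <- fit_tissue_gmm(ph$image, init_means = c(40, 110, 170))
  m2 <- fit_tissue_gmm(ph$image, init_means = c(170, 40, 110))
  expect_equal(m1$means, m2$means, tolerance = 1e-6)
  expect_equal(m1$p_gm, m2$p_gm, tolerance = 1e-6)
})

test_that("per-class voxel counts at default noise stay within 2% of truth", {
  ph <- test_phantom(seed = 4)
  maps <- fit_tissue_gmm(ph$image)
  lab <- ph$truth$label_volume
  vv <- prod(ph$image$voxel_size)
  expect_equal(tissue_volume(maps, "GM") / (sum(lab == 1L) * vv), 1,
               tolerance = 0.02)
  expect_equal(tissue_volume(maps, "WM") / (sum(lab == 2L) * vv), 1,
               tolerance = 0.02)
  expect_equal(tissue_volume(maps, "CSF") / (sum(lab %in% c(3L, 4L)) * vv), 1,
               tolerance = 0.02)
})

test_that("constant images are rejected as degenerate", {
  img <- vm_volume(array(7, c(16, 16, 16)))
  expect_error(fit_tissue_gmm(img), class = "vm_segmentation_error")
})

test_that("tissue_volume applies the posterior > 0.5 counting rule", {
  ph <- test_phantom(seed = 5)
  maps <- fit_tissue_gmm(ph$image)
  # zeroed maps count nothing
  zero <- maps
  zero$p_gm[] <- 0
  expect_equal(tissue_volume(zero, "GM"), 0)
  # 3 voxels above threshold at unit voxels
  m2 <- maps
  m2$p_wm[] <- 0
  m2$p_wm[c(1, 5, 9)] <- 0.6
  m2$voxel_size <- c(1, 1, 1)
  expect_equal(tissue_volume(m2, "WM"), 3)
  # random map equals the exhaustive voxel loop
  set.seed(31)
  m3 <- maps
  m3$p_csf <- array(runif(length(maps$p_csf)), dim(maps$p_csf))
  expect_equal(tissue_volume(m3, "CSF"),
               brute_tissue_volume(m3$p_csf, m3$voxel_size))
  expect_error(tissue_volume(maps, "bone"), class = "vm_parameter_error")
})

test_that("adding supra-threshold voxels never decreases a tissue volume", {
  ph <- test_phantom(seed = 6)
  maps <- fit_tissue_gmm(ph$image)
  v0 <- tissue_volume(maps, "GM")
  below <- which(maps$p_gm <= 0.5)
  maps$p_gm[below[1:10]] <- 0.9
  expect_gte(tissue_volume(maps, "GM"), v0)
})

test_that("noise-free region growing recovers the true cavity exactly", {
  ph <- test_phantom(seed = 7, noise_sd = 0)
  maps <- fit_tissue_gmm(ph$image)
  mask <- extract_ventricle(ph$image, maps, t_low = 30, t_high = 50,
                            morphology = FALSE)
  expect_identical(mask$mask, array(as.integer(ph$truth$label_volume == 4L),
                                    dim(ph$truth$label_volume)))
  expect_equal(ventricle_volume(mask), ph$truth$true_volumes[["ventricle"]])
})

test_that("region growing is stable under the choice of in-cavity seed", {
  ph <- test_phantom(seed = 8, noise_sd = 0)
  maps <- fit_tissue_gmm(ph$image)
  m1 <- extract_ventricle(ph$image, maps)
  alt <- which(m1$mask == 1L, arr.ind = TRUE)
  m2 <- extract_ventricle(ph$image, maps, seed_point = alt[nrow(alt) %/% 2, ])
  expect_identical(m1$mask, m2$mask)
})

test_that("an excluding threshold band raises an empty-mask error", {
  ph <- test_phantom(seed = 9)
  maps <- fit_tissue_gmm(ph$image)
  expect_error(extract_ventricle(ph$image, maps, t_low = 1e5, t_high = 2e5),
               class = "vm_empty_mask_error")
})

test_that("ventricle Dice against phantom truth reaches 0.90 at default noise", {
  for (seed in c(21, 22)) {
    ph <- test_phantom(seed = seed)
    maps <- fit_tissue_gmm(ph$image)
    mask <- extract_ventricle(ph$image, maps)
    expect_gte(dice(mask, truth_ventricle_mask(ph)), 0.90)
  }
})

test_that("slice-wise Sobel edges outline a square and respect morphology
          bounds", {
  arr <- array(0L, c(9, 9, 3))
  arr[3:7, 3:7, 2] <- 1L
  edges <- ventricle_edges(vm_mask(arr))
  ring <- array(0L, c(9, 9, 3))
  ring[3:7, 3:7, 2] <- 1L
  ring[4:6, 4:6, 2] <- 0L  # interior of the 5x5 square is edge-free
  expect_identical(edges$mask, ring)
  # empty in, empty out
  empty <- ventricle_edges(vm_mask(array(0L, c(5, 5, 2))))
  expect_equal(sum(empty$mask), 0L)
  # full slice: edges only at the slice border
  full <- array(1L, c(6, 6, 1))
  fe <- ventricle_edges(vm_mask(full))
  expect_true(all(fe$mask[2:5, 2:5, 1] == 0L))
  expect_true(all(fe$mask[c(1, 6), , 1] == 1L))
  expect_true(all(fe$mask[, c(1, 6), 1] == 1L))
})

test_that("ventricle_volume is voxel count times voxel volume", {
  arr <- array(0L, c(4, 4, 4))
  expect_equal(ventricle_volume(vm_mask(arr, c(2, 2, 2))), 0)
  arr[1:10] <- 1L
  expect_equal(ventricle_volume(vm_mask(arr, c(2, 2, 2))), 80)
})
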