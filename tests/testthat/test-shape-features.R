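make_masks <- function(n, dims = c(6, 7, 4), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    array(as.integer(runif(prod(dims)) > 0.5), dims))
}

test_that("probability maps are voxelwise mask means", {
  m <- make_masks(1)[[1]]
  pm <- build_probability_map(list(m), group = "NC")
  expect_equal(pm$values, m)
  # complementary masks: 0.5 on the symmetric difference, 1 on both, 0 outside
  a <- array(0L, c(4, 4, 2)); a[1:10] <- 1L
  b <- array(1L - a, dim(a))
  pm2 <- build_probability_map(list(a, b))
  expect_true(all(pm2$values[a != b] == 0.5))
  both <- a == 1L & b == 1L
  expect_true(all(pm2$values[both] == 1))
  # 10 random masks equal the exhaustive mean
  ms <- make_masks(10, seed = 5)
  pm3 <- build_probability_map(ms)
  expect_equal(pm3$values, Reduce(`+`, ms) / 10)
  expect_equal(pm3$n_train, 10L)
  expect_error(build_probability_map(list(a, array(0L, c(3, 3, 3)))),
               class = "vm_grid_error")
})

test_that("discriminate maps subtract control from patient and are
          antisymmetric", {
  ms <- make_masks(4, seed = 2)
  p1 <- build_probability_map(ms[1:2], "AD")
  p2 <- build_probability_map(ms[3:4], "NC")
  expect_true(all(discriminate_map(p1, p1)$values == 0))
  d12 <- discriminate_map(p1, p2)
  d21 <- discriminate_map(p2, p1)
  expect_equal(d12$values, -d21$values)
  expect_true(all(d12$values >= -1 & d12$values <= 1))
})

test_that("enlarged-cavity phantoms score positive against controls at the
          cavity margin", {
  nc <- lapply(1:3, function(s)
    truth_ventricle_mask(test_phantom(seed = s, ventricle_scale = 1)))
  ad <- lapply(4:6, function(s)
    truth_ventricle_mask(test_phantom(seed = s, ventricle_scale = 1.6)))
  dm <- discriminate_map(build_probability_map(ad, "AD"),
                         build_probability_map(nc, "NC"))
  margin <- Reduce(`&`, lapply(ad, function(m) m$mask == 1L)) &
    !Reduce(`|`, lapply(nc, function(m) m$mask == 1L))
  expect_gt(sum(margin), 0)
  expect_true(all(dm$values[margin] > 0))
  # a large-cavity test subject matches the AD template better
  test_ad <- truth_ventricle_mask(test_phantom(seed = 9, ventricle_scale = 1.6))
  test_nc <- truth_ventricle_mask(test_phantom(seed = 10, ventricle_scale = 1))
  expect_gt(matching_coefficient(dm, test_ad), matching_coefficient(dm, test_nc))
})

test_that("the matching coefficient is the exhaustive voxel inner product
          and is linear in the map", {
  ms <- make_masks(2, seed = 3)
  p1 <- build_probability_map(ms[1], "AD")
  p2 <- build_probability_map(ms[2], "NC")
  dm <- discriminate_map(p1, p2)
  tmask <- make_masks(1, seed = 4)[[1]]
  expect_equal(matching_coefficient(dm, tmask),
               brute_matching_coefficient(dm$values, tmask))
  # zero map
  z <- dm; z$values[] <- 0
  expect_equal(matching_coefficient(z, tmask), 0)
  # single voxel of 0.5
  s <- dm; s$values[] <- 0; s$values[2, 3, 1] <- 0.5
  one <- array(1L, dim(s$values))
  expect_equal(matching_coefficient(s, one), 0.5)
  # linearity in the discriminate map
  d1 <- dm; d2 <- dm
  set.seed(6)
  d1$values <- array(runif(length(dm$values), -1, 1), dim(dm$values))
  d2$values <- array(runif(length(dm$values), -1, 1), dim(dm$values))
  comb <- dm
  comb$values <- 2 * d1$values - 3 * d2$values
  expect_equal(matching_coefficient(comb, tmask),
               2 * matching_coefficient(d1, tmask) -
                 3 * matching_coefficient(d2, tmask))
})

test_that("the datum slice is the first axial slice of maximum area", {
  arr <- array(0L, c(5, 5, 4))
  arr[1:3, 1, 2] <- 1L      # 3 pixels
  arr[1:3, 1:2, 3] <- 1L    # 6 pixels
  expect_equal(datum_slice(vm_mask(arr)), 3L)
  # tie rule: first of the maxima
  arr[1:3, 1:2, 2] <- 1L
  expect_equal(datum_slice(vm_mask(arr)), 2L)
  expect_error(datum_slice(vm_mask(array(0L, c(4, 4, 4)))),
               class = "vm_empty_mask_error")
  # phantom mask equals the independent per-slice argmax
  ph <- test_phantom(seed = 12)
  m <- truth_ventricle_mask(ph)
  sums <- sapply(seq_len(dim(m$mask)[3]), function(z) sum(m$mask[, , z]))
  expect_equal(datum_slice(m), which.max(sums))
})

test_that("a filled square yields the closed-form descriptors", {
  sq <- matrix(0, 12, 12)
  sq[2:11, 2:11] <- 1
  s <- shape2d(sq, pixel_size = 1)
  expect_equal(s$area, 100)
  expect_equal(s$perimeter, 36)  # traced boundary ring of the 10x10 square
  expect_equal(s$circularity, 100 * 4 * pi * 100 / 36^2)
  expect_equal(s$elongation, 1)
  expect_equal(s$rectangularity, 1, tolerance = 1e-9)
  expect_equal(s$min_thickness, 10, tolerance = 1e-6)
  expect_equal(s$area_pr + s$area_pl + s$area_fr + s$area_fl, s$area)
})

test_that("a 20x5 rectangle has elongation 4 and diagonal extreme distance", {
  rc <- matrix(0, 24, 9)
  rc[3:22, 3:7] <- 1
  s <- shape2d(rc, pixel_size = 1)
  expect_equal(s$elongation, 4, tolerance = 1e-9)
  expect_equal(s$d_ac, sqrt(19^2 + 4^2))
  expect_equal(s$rectangularity, 1, tolerance = 1e-9)
  expect_equal(s$min_thickness, 5, tolerance = 1e-6)
  expect_equal(s$area, 100)
})

test_that("a digital disk is near-circular", {
  n <- 41
  xy <- expand.grid(x = 1:n, y = 1:n)
  disk <- matrix(as.numeric((xy$x - 21)^2 + (xy$y - 21)^2 <= 15^2), n, n)
  s <- shape2d(disk, pixel_size = 1)
  expect_gt(s$circularity, 90)
  expect_lt(s$circularity, 110)
  expect_lt(s$elongation, 1.05)
  expect_equal(s$mean_signature, 15, tolerance = 0.05)
  expect_equal(s$min_thickness, 30, tolerance = 0.05)
})

test_that("descriptors scale correctly with pixel size", {
  ph <- test_phantom(seed = 13)
  m <- truth_ventricle_mask(ph)
  sl <- m$mask[, , datum_slice(m)]
  s1 <- shape2d(sl, pixel_size = 1)
  s2 <- shape2d(sl, pixel_size = 2)
  for (f in c("area", "area_pr", "area_pl", "area_fr", "area_fl"))
    expect_equal(s2[[f]], 4 * s1[[f]])
  for (f in c("perimeter", "d_ag", "d_bg", "d_cg", "d_dg", "d_ac", "d_bd",
              "min_thickness", "mean_signature"))
    expect_equal(s2[[f]], 2 * s1[[f]])
  for (f in c("circularity", "elongation", "rectangularity"))
    expect_equal(s2[[f]], s1[[f]])
})

test_that("rotation by 90 degrees preserves scalar descriptors and mirroring
          swaps left/right sub-areas", {
  ph <- test_phantom(seed = 14)
  m <- truth_ventricle_mask(ph)
  sl <- m$mask[, , datum_slice(m)]
  s <- shape2d(sl, 1)
  rot <- t(sl)[ncol(sl):1, , drop = FALSE]  # 90 degree rotation
  sr <- shape2d(rot, 1)
  expect_equal(sr$area, s$area)
  expect_equal(sr$perimeter, s$perimeter, tolerance = 1e-9)
  expect_equal(sr$circularity, s$circularity, tolerance = 1e-9)
  expect_equal(sr$elongation, s$elongation, tolerance = 1e-9)
  expect_equal(sr$rectangularity, s$rectangularity, tolerance = 1e-6)
  expect_equal(sr$min_thickness, s$min_thickness, tolerance = 1e-6)
  mir <- sl[nrow(sl):1, , drop = FALSE]     # left-right mirror
  sm <- shape2d(mir, 1)
  expect_equal(sm$area_pr, s$area_pl)
  expect_equal(sm$area_pl, s$area_pr)
  expect_equal(sm$area_fr, s$area_fl)
  expect_equal(sm$area_fl, s$area_fr)
})

test_that("degenerate and empty slices follow the stated conventions", {
  expect_error(shape2d(matrix(0, 4, 4)), class = "vm_empty_mask_error")
  px <- matrix(0, 5, 5); px[3, 3] <- 1
  s <- shape2d(px, 1)
  expect_equal(s$elongation, 1)
  expect_equal(s$d_ag, 0)
  expect_equal(s$d_ac, 0)
  expect_equal(s$circularity, 100)
  expect_equal(s$area, 1)
})

test_that("phantom cohort group means of area and extreme distance are
          monotone NC < MCI < AD", {
  co <- generate_cohort(n_per_group = 4, seed = 17)
  rows <- t(vapply(co$subjects, function(s) {
    m <- truth_ventricle_mask(s)
    sh <- shape2d(m$mask[, , datum_slice(m)], s$image$voxel_size[1])
    c(area = sh$area, d_ac = sh$d_ac)
  }, numeric(2)))
  g <- co$manifest$group
  expect_lt(mean(rows[g == "NC", "area"]), mean(rows[g == "MCI", "area"]))
  expect_lt(mean(rows[g == "MCI", "area"]), mean(rows[g == "AD", "area"]))
  expect_lt(mean(rows[g == "NC", "d_ac"]), mean(rows[g == "MCI", "d_ac"]))
  expect_lt(mean(rows[g == "MCI", "d_ac"]), mean(rows[g == "AD", "d_ac"]))
})
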