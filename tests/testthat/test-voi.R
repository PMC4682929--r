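host <- volume_grid(array(1, c(31, 31, 31)), unit = "suv")

test_that("sphere membership matches direct offset enumeration", {
  # independent enumeration: voxel centers within (d-1)/2 of the center
  expected_count <- function(d) {
    r <- (d - 1) / 2
    off <- expand.grid(-r:r, -r:r, -r:r)
    sum(rowSums(off^2) <= r^2)
  }
  expect_equal(sphere_voi(host, c(16, 16, 16), 1)$voxel_count, 1L)
  expect_equal(sphere_voi(host, c(16, 16, 16), 3)$voxel_count, 7L)
  for (d in seq(3, 17, 2)) {
    expect_equal(sphere_voi(host, c(16, 16, 16), d)$voxel_count,
                 expected_count(d))
  }
})

test_that("sphere counts are non-decreasing in diameter and masks are congruent translates", {
  counts <- vapply(seq(1, 17, 2), function(d)
    sphere_voi(host, c(16, 16, 16), d)$voxel_count, integer(1))
  expect_true(all(diff(counts) >= 0))

  centers <- rbind(c(10, 10, 10), c(16, 16, 16), c(20, 12, 18),
                   c(12, 20, 14), c(18, 18, 20))
  masks <- apply(centers, 1, function(ct) sphere_voi(host, ct, 9))
  expect_equal(length(unique(vapply(masks, `[[`, integer(1), "voxel_count"))), 1L)
  ref <- which(masks[[1]]$mask, arr.ind = TRUE)
  for (i in 2:5) {
    got <- which(masks[[i]]$mask, arr.ind = TRUE)
    shift <- centers[i, ] - centers[1, ]
    expect_equal(got, sweep(ref, 2, shift, "+"), ignore_attr = TRUE)
  }
})

test_that("invalid spheres are rejected", {
  expect_error(sphere_voi(host, c(16, 16, 16), 4), "odd")
  expect_error(sphere_voi(host, c(2, 16, 16), 9), "clipped")
})

test_that("metabolic volume is voxel count times voxel volume", {
  one <- sphere_voi(host, c(16, 16, 16), 1)
  expect_equal(metabolic_volume(one, c(4, 4, 4)), 0.064)
  m <- voi_mask(array(rep(c(TRUE, FALSE), c(39, 31^3 - 39)), c(31, 31, 31)))
  expect_equal(metabolic_volume(m, c(4, 4, 4)), 2.496)  # just under 2.5 mL
  m700 <- voi_mask(array(rep(c(TRUE, FALSE), c(700, 31^3 - 700)), c(31, 31, 31)))
  expect_equal(metabolic_volume(m700, c(4, 4, 4)), 44.8)
  # exact proportionality in voxel count
  expect_equal(metabolic_volume(m700, c(4, 4, 4)) / 700,
               metabolic_volume(m, c(4, 4, 4)) / 39)
})

test_that("adaptive threshold on a uniform lesion keeps every lesion voxel", {
  v <- array(0, c(21, 21, 21))
  x <- (1:21 - 11) * 4
  rho <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  v[rho <= 16] <- 10
  vol <- volume_grid(v, unit = "suv")
  seg <- adaptive_threshold_segment(vol, c(11, 11, 11), beta = 0.3,
                                    box_halfwidth = 6L)
  prov <- attr(seg, "segmentation")
  expect_equal(prov$threshold_suv, 3)      # 0.3 * 10 + background 0
  expect_equal(seg$voxel_count, sum(v == 10))
})

test_that("segmentation of a PSF-blurred sphere recovers its volume within 20%", {
  dims <- c(44, 44, 44)
  x <- (1:44 - 22.5) * 4
  rho <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  sph <- array(0, dims)
  sph[rho <= 28] <- 8
  blurred <- pettex:::smooth_gaussian_3d(sph, pettex:::fwhm_to_sigma_vox(7, c(4, 4, 4)))
  seg <- adaptive_threshold_segment(volume_grid(blurred, unit = "suv"),
                                    c(22, 22, 22), beta = 0.3)
  expect_lt(abs(seg$voxel_count - sum(rho <= 28)) / sum(rho <= 28), 0.2)
})

test_that("segmentation errors on empty uptake and is a single 26-connected component", {
  vol0 <- volume_grid(array(0, c(15, 15, 15)), unit = "suv")
  expect_error(adaptive_threshold_segment(vol0, c(8, 8, 8)), "empty segmentation")

  # two bright blobs: only the component under the local maximum is returned
  v <- array(0, c(25, 13, 13))
  v[4:6, 5:7, 5:7] <- 6
  v[18:21, 5:7, 5:7] <- 5
  seg <- adaptive_threshold_segment(volume_grid(v, unit = "suv"), c(5, 6, 6),
                                    box_halfwidth = 4L)
  expect_true(all(which(seg$mask, arr.ind = TRUE)[, 1] <= 6))
  # the component matches an independent flood fill over the thresholded set
  thr <- attr(seg, "segmentation")$threshold_suv
  la <- array(NA_integer_, dim(v)); la[v >= thr & v == 6] <- 1L
  zones <- oracle_zones(la)
  expect_equal(seg$voxel_count, zones[1, 2])
})

test_that("relocation preserves geometry exactly and clips loudly", {
  m <- sphere_voi(host, c(10, 10, 10), 7)
  same <- relocate_voi(m, c(10, 10, 10))
  expect_identical(same$mask, m$mask)
  moved <- relocate_voi(m, c(22, 18, 15))
  expect_equal(moved$voxel_count, m$voxel_count)
  a <- which(m$mask, arr.ind = TRUE)
  b <- which(moved$mask, arr.ind = TRUE)
  expect_equal(sweep(b, 2, c(12, 8, 5), "-"), a, ignore_attr = TRUE)
  expect_error(relocate_voi(m, c(30, 30, 30)), "clips")
})
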