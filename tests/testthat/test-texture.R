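test_that("direction set is the 13 sign-free unit-Chebyshev displacements", {
  d <- texture_directions()
  expect_identical(dim(d), c(13L, 3L))
  expect_true(all(apply(abs(d), 1, max) == 1))
  # no duplicates and no +/- pairs
  keys <- apply(d, 1, paste, collapse = ",")
  neg_keys <- apply(-d, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_false(any(neg_keys %in% keys))
})

test_that("the 1x1x3 row with levels 1,1,2 matches the hand enumeration", {
  la <- array(c(1L, 1L, 2L), c(3, 1, 1))
  dirs <- texture_directions()
  axis <- which(rownames(dirs) == "1,0,0")

  cm <- build_cm(la, dirs)
  expect_equal(cm$matrices[[axis]],
               matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(!vapply(cm$matrices, is.null, logical(1))), 1L)
  expect_equal(unname(cm_indices(cm)), c(0.75, 1.5, 0.5))

  gr <- build_grlm(la, dirs)
  expect_equal(gr$matrices[[axis]], matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gr$H[axis], 2L)
  one <- structure(list(matrices = gr$matrices[axis], H = gr$H[axis], L = 2L),
                   class = "grlm_set")
  expect_equal(unname(grlm_indices(one)), c(0.625, 2.5, 1))

  gz <- build_gzlm(la)
  expect_equal(gz$Z, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gz$H, 2L)
  expect_equal(unname(gzlm_indices(gz)), c(0.625, 2.5))
})

test_that("constant and degenerate VOIs hit their closed forms", {
  la <- array(1L, c(3, 3, 3))
  expect_equal(unname(cm_indices(build_cm(la))), c(1, 0, 0))
  gz <- build_gzlm(la)
  expect_equal(gz$H, 1L)
  expect_equal(dim(gz$Z), c(1L, 27L))

  single <- array(1L, c(1, 1, 1))
  cm1 <- build_cm(single)
  expect_true(cm1$degenerate)
  expect_error(cm_indices(cm1), "degenerate")

  # a 1x1xN constant row is one run of length N along its axis:
  # SRE = 1/N^2, LRE = N^2 for that direction; orthogonal directions give
  # N runs of length 1
  N <- 6
  row <- array(1L, c(1, 1, N))
  gr <- build_grlm(row)
  axis <- which(rownames(texture_directions()) == "0,0,1")
  one <- structure(list(matrices = gr$matrices[axis], H = gr$H[axis], L = 1L),
                   class = "grlm_set")
  expect_equal(unname(grlm_indices(one)), c(1 / N^2, N^2, 1))
  ortho <- which(rownames(texture_directions()) == "1,0,0")
  expect_equal(gr$H[ortho], N)
})

test_that("checkerboard zones merge diagonally under 26-connectivity but not 6", {
  la <- array(0L, c(4, 4, 4))
  idx <- which(la == 0, arr.ind = TRUE)
  la[] <- 1L + (rowSums(idx) %% 2L)
  z26 <- build_gzlm(la, connectivity = 26L)
  expect_equal(z26$H, 2L)                     # each parity one diagonal zone
  z6 <- build_gzlm(la, connectivity = 6L)
  expect_equal(z6$H, 64L)                     # face-adjacency never joins
})

test_that("matrices and indices are invariant under the 48 lattice symmetries", {
  set.seed(5)
  la <- random_level_lattice(c(5, 4, 3), n_levels = 4, mask_prob = 0.7)
  ref_cm <- cm_indices(build_cm(la))
  ref_gr <- grlm_indices(build_grlm(la))
  ref_gz <- gzlm_indices(build_gzlm(la))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (perm in perms) {
    for (fl in 0:7) {
      flips <- as.logical(bitwAnd(fl, c(1L, 2L, 4L)))
      t_la <- aperm(la, perm)
      sub <- lapply(seq_along(dim(t_la)), function(a) {
        if (flips[a]) rev(seq_len(dim(t_la)[a])) else seq_len(dim(t_la)[a])
      })
      t_la <- t_la[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
      expect_equal(cm_indices(build_cm(t_la)), ref_cm, tolerance = 1e-12)
      expect_equal(grlm_indices(build_grlm(t_la)), ref_gr, tolerance = 1e-12)
      expect_equal(gzlm_indices(build_gzlm(t_la)), ref_gz, tolerance = 1e-12)
    }
  }
})

test_that("zone mass conservation and index bounds hold on random lattices", {
  set.seed(9)
  for (i in 1:40) {
    la <- random_level_lattice(c(4, 5, 4), n_levels = 6, mask_prob = runif(1, 0.3, 0.9))
    n_vox <- sum(!is.na(la))
    gz <- build_gzlm(la)
    j <- seq_len(ncol(gz$Z))
    expect_equal(sum(colSums(gz$Z) * j), n_vox)

    gr <- build_grlm(la)
    for (k in seq_along(gr$matrices)) {
      jk <- seq_len(ncol(gr$matrices[[k]]))
      cs <- colSums(gr$matrices[[k]])
      h <- gr$H[k]
      sre <- sum(cs / jk^2) / h
      lre <- sum(cs * jk^2) / h
      expect_lte(sre, 1)
      expect_gte(lre, 1)
      # every in-mask voxel is in exactly one run per direction
      expect_equal(sum(cs * jk), n_vox)
    }

    cm <- build_cm(la)
    for (m in cm$matrices) if (!is.null(m)) expect_equal(sum(m), 1)
    if (!cm$degenerate) expect_lte(cm_indices(cm)[["homogeneity"]], 1)
  }
})

test_that("extract_ti composes resampling, matrices and provenance", {
  set.seed(21)
  vals <- array(runif(11^3, 1, 12), c(11, 11, 11))
  vol <- volume_grid(vals, unit = "suv")
  mask <- sphere_voi(vol, c(6, 6, 6), 9)
  rr <- extract_ti(vol, mask, resampling_preset("rr"), voi_id = "x")
  ar <- extract_ti(vol, mask, resampling_preset("ar20"), voi_id = "x")
  # SUV statistics are resampling-independent, texture is not
  expect_equal(rr$suvmax, ar$suvmax)
  expect_equal(rr$mv, ar$mv)
  expect_false(isTRUE(all.equal(rr$entropy, ar$entropy)))

  # doubling the SUV scale (AR20): suvmax doubles, AR texture moves,
  # RR texture is untouched
  vol2 <- volume_grid(2 * vals, unit = "suv")
  rr2 <- extract_ti(vol2, mask, resampling_preset("rr"))
  ar2 <- extract_ti(vol2, mask, resampling_preset("ar20"))
  expect_equal(ar2$suvmax, 2 * ar$suvmax)
  expect_equal(unlist(rr2[ti_index_names()]), unlist(rr[ti_index_names()]))
  expect_false(isTRUE(all.equal(ar2$entropy, ar$entropy)))

  df <- as.data.frame(ar)
  expect_identical(names(df),
    c("voi_id", "method", "D", "low", "high", "homogeneity", "entropy",
      "contrast", "sre", "lre", "rlnu", "lgze", "hgze", "suvmax_suv",
      "mv_ml", "n_voxels", "n_clipped"))
  expect_equal(df$method, "AR20")
  expect_equal(df$n_voxels, mask$voxel_count)
})

test_that("constant VOI texture vector hits the closed forms at its AR level", {
  g_suv <- 10; D <- 64
  vol <- volume_grid(array(g_suv, c(6, 6, 6)), unit = "suv")
  mask <- voi_mask(array(TRUE, c(6, 6, 6)))
  ti <- extract_ti(vol, mask, resampling_spec("AR", D, 0, 20))
  g <- round(D * g_suv / 20) + 1           # the single occupied level
  expect_equal(ti$homogeneity, 1)
  expect_equal(ti$entropy, 0)
  expect_equal(ti$contrast, 0)
  expect_equal(ti$lgze, 1 / g^2)
  expect_equal(ti$hgze, g^2)
  expect_equal(ti$suvmax, g_suv)
})
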