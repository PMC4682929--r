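make_features <- function(n, method = "AR20", seed = 1) {
  set.seed(seed)
  df <- data.frame(voi_id = sprintf("v%02d", 1:n), method = method)
  for (ix in ti_index_names()) df[[ix]] <- runif(n)
  df$suvmax_suv <- runif(n, 2, 15)
  df$mv_ml <- runif(n, 3, 80)
  df$n_voxels <- as.integer(df$mv_ml / 0.064)
  df
}

test_that("Spearman profiles agree with rank arithmetic and flag degeneracy", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    x <- sample(round(runif(n, 0, 10), 1))   # ties likely
    y <- rnorm(n)
    expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
                 oracle_spearman(x, y), tolerance = 1e-12)
  }
  f <- make_features(12)
  f$entropy <- rank(f$n_voxels)              # strictly increasing in volume
  prof <- spearman_profile(f, "n_voxels")
  expect_equal(prof$r[prof$index == "entropy"], 1)
  f$sre <- 0.5                               # zero variance
  prof2 <- spearman_profile(f, "n_voxels")
  expect_equal(prof2$r[prof2$index == "sre"], 0)
  expect_true(prof2$degenerate[prof2$index == "sre"])
  expect_error(spearman_profile(f[1:2, ], "n_voxels"), "fewer than 3")
})

test_that("the MV cap restricts correlation profiles to small VOIs", {
  f <- make_features(30)
  prof <- spearman_profile(f, "n_voxels", mv_cap = 60)
  expect_equal(unique(prof$n), sum(f$mv_ml < 60))
  prof_all <- spearman_profile(f, "n_voxels")
  expect_equal(unique(prof_all$n), 30L)
})

test_that("Wilcoxon p-values match exact enumeration for small samples", {
  set.seed(14)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = TRUE))$p.value
    expect_equal(got, oracle_signed_rank_p(x, y), tolerance = 1e-12)
    m <- sample(4:6, 1)
    a <- rnorm(m); b <- rnorm(sample(4:6, 1), mean = 0.5)
    got2 <- suppressWarnings(wilcox.test(a, b, exact = TRUE))$p.value
    expect_equal(got2, oracle_rank_sum_p(a, b), tolerance = 1e-12)
  }
})

test_that("group comparisons separate shifted distributions and not identical ones", {
  set.seed(30)
  a <- make_features(30, seed = 2)
  b <- make_features(30, seed = 3)
  for (ix in ti_index_names()) b[[ix]] <- b[[ix]] + 3   # 3 pooled SDs apart
  cmp <- compare_groups(a, b, labels = c("lo", "hi"))
  expect_true(all(cmp$p_value[cmp$index %in% ti_index_names()] < 0.001))
  same <- compare_groups(a, a, labels = c("x", "y"))
  expect_true(all(same$p_value > 0.9))

  # fixed row set and ordering: 7 TI + SUVmax (+ MV when unpaired)
  expect_identical(same$index, c("homogeneity", "entropy", "sre", "lre",
                                 "rlnu", "lgze", "hgze", "suvmax_suv", "mv_ml"))
  paired <- compare_groups(a, b, labels = c("t", "l"), paired = TRUE)
  expect_identical(paired$index, c("homogeneity", "entropy", "sre", "lre",
                                   "rlnu", "lgze", "hgze", "suvmax_suv"))
  expect_error(compare_groups(a[1:5, ], b, paired = TRUE), "equal group sizes")
})

test_that("phantom experiment output is coherent and AR is no more volume-bound than RR", {
  pe <- cached_phantom_experiment()
  expect_equal(sort(unique(pe$features$diameter)), seq(3, 17, 2))
  expect_equal(length(unique(pe$features$position)), 5L)
  # per diameter, 5 positions x 2 methods
  expect_equal(nrow(pe$features), 8 * 5 * 2)
  co <- pe$correlations
  for (ix in c("homogeneity", "entropy")) {
    r_rr <- abs(co$r[co$method == "RR" & co$index == ix])
    r_ar <- abs(co$r[co$method == "AR20" & co$index == ix])
    expect_lte(r_ar, r_rr)
  }
  # means/sds are over exactly the 5 positions
  s <- pe$summary
  expect_equal(nrow(s), 8 * 2 * length(ti_index_names()))
})

test_that("cohort experiment emits aligned paired tables and deterministic output", {
  ce <- cached_cohort_experiment()
  f <- ce$features
  # every retained patient contributes one tumor and one liver row per method
  tab <- table(f$tissue, f$method)
  expect_true(all(tab == tab[1, 1]))
  # paired rows aligned by patient id
  t_ids <- sort(unique(f$voi_id[f$tissue == "tumor"]))
  l_ids <- sort(unique(f$voi_id[f$tissue == "liver"]))
  expect_identical(t_ids, l_ids)
  # tumor and relocated liver VOIs share their voxel count patient by patient
  f20 <- f[f$method == "AR20", ]
  t20 <- f20[f20$tissue == "tumor", ]; l20 <- f20[f20$tissue == "liver", ]
  expect_equal(t20$n_voxels[order(t20$voi_id)], l20$n_voxels[order(l20$voi_id)])
  expect_equal(nrow(ce$exclusions), 2L)
  expect_true(all(c("tumor_vs_liver", "adeno_vs_squamous", "quartiles",
                    "correlations", "sign_pattern") %in% names(ce)))
})
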