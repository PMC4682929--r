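# Statistical characterization layer: correlation of texture indices with
# VOI volume and SUVmax, Wilcoxon tissue/subtype comparisons, and the two
# end-to-end experiments (uniform phantom, synthetic cohort).

comparison_index_names <- function(include_mv = FALSE) {
  idx <- c("homogeneity", "entropy", "sre", "lre", "rlnu", "lgze", "hgze",
           "suvmax_suv")
  if (include_mv) idx <- c(idx, "mv_ml")
  idx
}

spearman_r <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = 0, degenerate = TRUE))
  list(r = stats::cor(x, y, method = "spearman"), degenerate = FALSE)
}

#' Spearman correlation profile of texture indices
#'
#' For each resampling method and index in a feature table, computes the
#' Spearman rank correlation between the index and either the VOI voxel
#' count or SUVmax. An optional metabolic-volume cap (default 60 mL for
#' tumor profiles) restricts the points to the regime where volume dependence
#' matters. A zero-variance index is reported as r = 0 with a degenerate
#' flag rather than an error, so profile tables always render.
#'
#' @param features Feature table (rows from [as.data.frame.ti_vector()],
#'   typically with added grouping columns).
#' @param target `"n_voxels"` or `"suvmax"`.
#' @param mv_cap Optional MV cap in mL (`NULL` for no cap).
#' @param indices Index columns to profile.
#' @return Data frame with one row per method x index: `r`, `n`,
#'   `degenerate`, `target`.
#' @export
spearman_profile <- function(features, target = c("n_voxels", "suvmax"),
                             mv_cap = NULL, indices = ti_index_names()) {
  target <- match.arg(target)
  stopifnot(is.data.frame(features))
  if (!is.null(mv_cap)) features <- features[features$mv_ml < mv_cap, , drop = FALSE]
  if (nrow(features) < 3L)
    stop("fewer than 3 points available for the correlation profile", call. = FALSE)
  tgt <- if (target == "n_voxels") features$n_voxels else features$suvmax_suv
  out <- do.call(rbind, lapply(split(seq_len(nrow(features)), features$method),
    function(rows) {
      do.call(rbind, lapply(indices, function(ix) {
        s <- spearman_r(features[[ix]][rows], tgt[rows])
        data.frame(method = features$method[rows[1]], index = ix,
                   target = target, r = s$r, n = length(rows),
                   degenerate = s$degenerate, stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Wilcoxon comparison of two feature groups
#'
#' Compares each index between two groups of VOIs with a two-sided Wilcoxon
#' test: signed-rank when `paired = TRUE` (same patients, same VOI geometry,
#' e.g. tumor vs relocated-liver), rank-sum otherwise (e.g. adenocarcinoma vs
#' squamous). Exact p-values are used for group sizes up to 25 and the
#' normal approximation with continuity correction above that. Group medians
#' and quartiles are reported alongside each p-value.
#'
#' @param features_a,features_b Feature tables for the two groups; under
#'   `paired = TRUE` they must have equal row counts, aligned by `voi_id`.
#' @param labels Group labels used in the output.
#' @param paired Signed-rank (`TRUE`) or rank-sum (`FALSE`).
#' @param indices Index columns to compare; by default the seven texture
#'   indices plus SUVmax, plus MV for unpaired comparisons.
#' @return Data frame with one row per index: test statistic, two-sided
#'   p-value, per-group median and quartiles, group sizes, pairing flag.
#' @export
compare_groups <- function(features_a, features_b,
                           labels = c("group_a", "group_b"), paired = FALSE,
                           indices = NULL) {
  stopifnot(is.data.frame(features_a), is.data.frame(features_b))
  if (is.null(indices)) indices <- comparison_index_names(include_mv = !paired)
  n_a <- nrow(features_a); n_b <- nrow(features_b)
  if (n_a < 2L || n_b < 2L)
    stop("each group must contain at least 2 VOIs", call. = FALSE)
  if (paired) {
    if (n_a != n_b)
      stop("paired comparison requires equal group sizes", call. = FALSE)
    if (!is.null(features_a$voi_id) && !is.null(features_b$voi_id) &&
        !identical(features_a$voi_id, features_b$voi_id))
      stop("paired comparison requires aligned voi_id", call. = FALSE)
  }
  exact <- min(n_a, n_b) <= 25L
  out <- do.call(rbind, lapply(indices, function(ix) {
    x <- features_a[[ix]]; y <- features_b[[ix]]
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE))
    qa <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(index = ix, statistic = unname(wt$statistic),
               p_value = wt$p.value,
               median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
               median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
               n_a = n_a, n_b = n_b, paired = paired,
               stringsAsFactors = FALSE)
  }))
  names(out) <- sub("_a$", paste0("_", labels[1]), names(out))
  names(out) <- sub("_b$", paste0("_", labels[2]), names(out))
  rownames(out) <- NULL
  out
}

#' Run the uniform-phantom experiment
#'
#' Simulates the phantom, draws spheres of every requested diameter at each
#' position, extracts the texture-index vector under each resampling method,
#' and summarizes: mean and standard deviation over positions per diameter,
#' the Spearman correlation of the per-diameter means against voxel count,
#' and a plateau flag per index. An index is considered to have plateaued
#' when the change between the two largest sphere sizes is below 5% of the
#' full range of its per-diameter means.
#'
#' @param spec A [phantom_spec()].
#' @param diameters Sphere diameters in voxels (odd), default 3 to 17.
#' @param centers Sphere centers, default [phantom_sphere_centers()].
#' @param methods Resampling preset names (see [resampling_preset()]).
#' @param D Number of gray levels.
#' @return A list of class `phantom_experiment`: `features` (per-sphere
#'   rows), `summary` (mean/sd per diameter), `correlations` (per
#'   method x index), `plateau` (per method x index), plus the spec and
#'   centers used.
#' @export
run_phantom_experiment <- function(spec = phantom_spec(),
                                   diameters = seq(3L, 17L, by = 2L),
                                   centers = NULL,
                                   methods = c("rr", "ar20"), D = 64L) {
  vol <- simulate_phantom(spec)
  if (is.null(centers))
    centers <- phantom_sphere_centers(spec, max_diameter = max(diameters))
  specs <- lapply(methods, resampling_preset, D = D)
  rows <- list()
  for (d in diameters) {
    for (p in seq_len(nrow(centers))) {
      mask <- sphere_voi(vol, centers[p, ], d)
      for (sp in specs) {
        ti <- extract_ti(vol, mask, sp, voi_id = sprintf("d%02d_%s", d, rownames(centers)[p]))
        row <- as.data.frame(ti)
        row$diameter <- d
        row$position <- rownames(centers)[p]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  features <- do.call(rbind, rows)

  idx <- ti_index_names()
  summ <- do.call(rbind, lapply(split(features, features[c("method", "diameter")]),
    function(g) {
      do.call(rbind, lapply(idx, function(ix) {
        data.frame(method = g$method[1], diameter = g$diameter[1],
                   n_voxels = g$n_voxels[1], index = ix,
                   mean = mean(g[[ix]]), sd = stats::sd(g[[ix]]),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$method, summ$index, summ$diameter), ]

  per_mi <- split(summ, summ[c("method", "index")])
  correlations <- do.call(rbind, lapply(per_mi, function(g) {
    s <- spearman_r(g$mean, g$n_voxels)
    data.frame(method = g$method[1], index = g$index[1], r = s$r,
               n = nrow(g), degenerate = s$degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(correlations) <- NULL

  plateau <- do.call(rbind, lapply(per_mi, function(g) {
    g <- g[order(g$diameter), ]
    m <- g$mean
    rng <- max(m) - min(m)
    last_change <- abs(m[length(m)] - m[length(m) - 1L])
    frac <- if (rng > 0) last_change / rng else 0
    data.frame(method = g$method[1], index = g$index[1],
               last_change_frac = frac, plateaued = frac < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(plateau) <- NULL

  structure(list(features = features, summary = summ,
                 correlations = correlations, plateau = plateau,
                 centers = centers, spec = spec),
            class = "phantom_experiment")
}

# Sign pattern of group medians: "+" where group a's median exceeds group
# b's, per index, for one resampling method.
median_sign_pattern <- function(features_a, features_b, method, indices) {
  a <- features_a[features_a$method == method, , drop = FALSE]
  b <- features_b[features_b$method == method, , drop = FALSE]
  vapply(indices, function(ix) {
    if (stats::median(a[[ix]]) > stats::median(b[[ix]])) "+" else "-"
  }, character(1))
}

#' Run the synthetic-cohort experiment
#'
#' End-to-end reproduction of the cohort analysis on synthetic data:
#' simulate the cohort, segment each tumor with the adaptive threshold,
#' apply the exclusion filters (delay window, minimum metabolic volume),
#' relocate each tumor mask into the patient's liver, extract texture-index
#' vectors under every requested resampling method, and assemble the
#' statistical outputs: paired tumor-vs-liver and unpaired
#' adenocarcinoma-vs-squamous Wilcoxon tables (with a Holm-adjusted column),
#' quartile summaries, Spearman profiles against voxel count (MV-capped) and
#' SUVmax, and the sign pattern of the group medians. Patients whose
#' segmentation or relocation fails are dropped and listed in the failure
#' manifest.
#'
#' @param spec A [cohort_spec()].
#' @param methods Resampling preset names.
#' @param beta Adaptive-threshold multiplier passed to
#'   [adaptive_threshold_segment()].
#' @param mv_cap MV cap (mL) for the tumor correlation profiles.
#' @param D Number of gray levels.
#' @param sign_method Method whose medians define the sign pattern.
#' @return A list of class `cohort_experiment` with elements `features`,
#'   `ledger`, `exclusions`, `tumor_vs_liver`, `adeno_vs_squamous`,
#'   `quartiles`, `correlations`, `sign_pattern`, `failures`.
#' @export
run_cohort_experiment <- function(spec = cohort_spec(),
                                  methods = c("rr", "ar15", "ar20", "ar25"),
                                  beta = 0.3, mv_cap = 60, D = 64L,
                                  sign_method = "AR20") {
  sim <- simulate_cohort(spec)
  ledger <- sim$ledger
  n <- nrow(ledger)
  failures <- list()
  tumor_masks <- vector("list", n)
  for (i in seq_len(n)) {
    seed_vox <- c(ledger$tumor_ci[i], ledger$tumor_cj[i], ledger$tumor_ck[i])
    res <- tryCatch(
      adaptive_threshold_segment(sim$volumes[[i]], seed_vox, beta = beta),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ledger$patient_id[i]]] <- paste("segmentation:", conditionMessage(res))
      next
    }
    tumor_masks[[i]] <- res
    ledger$mv_ml[i] <- metabolic_volume(res, sim$volumes[[i]]$spacing)
  }
  seg_ok <- !vapply(tumor_masks, is.null, logical(1))
  excl <- apply_exclusions(ledger[seg_ok, , drop = FALSE])
  keep_ids <- excl$ledger$patient_id

  specs <- lapply(methods, resampling_preset, D = D)
  rows <- list()
  for (i in which(seg_ok & ledger$patient_id %in% keep_ids)) {
    vol <- sim$volumes[[i]]
    tmask <- tumor_masks[[i]]
    lmask <- tryCatch(
      relocate_voi(tmask, c(ledger$liver_ci[i], ledger$liver_cj[i], ledger$liver_ck[i])),
      error = function(e) e)
    if (inherits(lmask, "error")) {
      failures[[ledger$patient_id[i]]] <- paste("relocation:", conditionMessage(lmask))
      next
    }
    for (sp in specs) {
      for (tissue in c("tumor", "liver")) {
        mask <- if (tissue == "tumor") tmask else lmask
        row <- as.data.frame(extract_ti(vol, mask, sp, voi_id = ledger$patient_id[i]))
        row$tissue <- tissue
        row$subtype <- ledger$subtype[i]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  features <- do.call(rbind, rows)
  if (is.null(features) || nrow(features) == 0L)
    stop("cohort experiment produced no features", call. = FALSE)

  split_tissue <- function(tissue) {
    f <- features[features$tissue == tissue, , drop = FALSE]
    f[order(f$method, f$voi_id), , drop = FALSE]
  }
  tum <- split_tissue("tumor"); liv <- split_tissue("liver")

  per_method <- function(f) split(f, f$method)
  tvl <- do.call(rbind, Map(function(ta, la) {
    cmp <- compare_groups(ta, la, labels = c("tumor", "liver"), paired = TRUE)
    cmp$method <- ta$method[1]
    cmp$p_holm <- stats::p.adjust(cmp$p_value, method = "holm")
    cmp
  }, per_method(tum), per_method(liv)))
  rownames(tvl) <- NULL

  avs <- do.call(rbind, lapply(per_method(tum), function(ta) {
    cmp <- compare_groups(ta[ta$subtype == "adeno", , drop = FALSE],
                          ta[ta$subtype == "squamous", , drop = FALSE],
                          labels = c("adeno", "squamous"), paired = FALSE)
    cmp$method <- ta$method[1]
    cmp$p_holm <- stats::p.adjust(cmp$p_value, method = "holm")
    cmp
  }))
  rownames(avs) <- NULL

  quart <- do.call(rbind, lapply(split(features, features[c("method", "tissue")]),
    function(g) {
      do.call(rbind, lapply(comparison_index_names(include_mv = TRUE), function(ix) {
        q <- stats::quantile(g[[ix]], c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(method = g$method[1], tissue = g$tissue[1], index = ix,
                   mean = mean(g[[ix]]), q1 = q[1], median = q[2], q3 = q[3],
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(quart) <- NULL

  correlations <- rbind(
    cbind(spearman_profile(tum, "n_voxels", mv_cap = mv_cap), tissue = "tumor"),
    cbind(spearman_profile(tum, "suvmax"), tissue = "tumor"),
    cbind(spearman_profile(liv, "n_voxels", mv_cap = mv_cap), tissue = "liver"))
  rownames(correlations) <- NULL

  if (!sign_method %in% features$method) sign_method <- features$method[1]
  sign_idx <- comparison_index_names()
  sign_tissue <- median_sign_pattern(tum, liv, sign_method, sign_idx)
  sign_idx_sub <- comparison_index_names(include_mv = TRUE)
  adeno <- tum[tum$subtype == "adeno", , drop = FALSE]
  squam <- tum[tum$subtype == "squamous", , drop = FALSE]
  sign_subtype <- median_sign_pattern(adeno, squam, sign_method, sign_idx_sub)
  sign_pattern <- data.frame(
    index = sign_idx_sub,
    tumor = c(sign_tissue, "N/A"),
    healthy = c(ifelse(sign_tissue == "+", "-", "+"), "N/A"),
    adeno = sign_subtype,
    squamous = ifelse(sign_subtype == "+", "-", "+"),
    stringsAsFactors = FALSE)

  structure(list(features = features, ledger = ledger,
                 exclusions = excl$tally,
                 tumor_vs_liver = tvl, adeno_vs_squamous = avs,
                 quartiles = quart, correlations = correlations,
                 sign_pattern = sign_pattern,
                 failures = failures, spec = spec),
            class = "cohort_experiment")
}

#' Plot texture-index profiles against VOI size
#'
#' Mean +/- SD of each index as a function of the sphere voxel count, one
#' panel per index, colored by resampling method. Requires ggplot2.
#'
#' @param experiment A `phantom_experiment` from [run_phantom_experiment()].
#' @param indices Indices to plot.
#' @return A ggplot object.
#' @export
plot_ti_profiles <- function(experiment,
                             indices = c("homogeneity", "entropy", "rlnu", "hgze")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  s <- experiment$summary
  s <- s[s$index %in% indices, , drop = FALSE]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n_voxels, y = .data$mean,
                                  color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "VOI voxel count", y = "index value",
                  color = "resampling") +
    ggplot2::theme_minimal()
}
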