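#' The 13 sign-free 3D displacement directions
#'
#' All displacement vectors with components in \{-1, 0, 1\}, excluding the
#' null vector and keeping one representative per +/- pair (the first
#' non-zero component is positive). Co-occurrence and run-length matrices are
#' computed once per direction at a distance of one voxel and the derived
#' indices are averaged over the directions.
#'
#' @return A 13 x 3 integer matrix, one direction per row.
#' @export
texture_directions <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nz <- apply(g, 1L, function(r) r[which(r != 0)[1]])
  d <- g[first_nz > 0, , drop = FALSE]
  storage.mode(d) <- "integer"
  rownames(d) <- apply(d, 1L, paste, collapse = ",")
  d
}

# Embed per-voxel gray levels into the mask geometry and crop to the mask
# bounding box: an integer array with NA outside the VOI.
level_array <- function(levels, mask) {
  la <- array(NA_integer_, dim(mask$mask))
  la[mask$mask] <- levels
  bb <- bbox_ranges(mask$mask)
  la[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
}

# Source-block index ranges so that every source voxel has its d-neighbor
# inside the lattice; NULL when the lattice is too thin for this direction.
shift_ranges <- function(dims, d) {
  out <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, 1L - d[a]); hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) return(NULL)
    out[[a]] <- lo:hi
  }
  out
}

#' Build per-direction co-occurrence matrices
#'
#' For each direction `d`, counts the ordered gray-level pairs
#' `(level(x), level(x + d))` for all voxels with both ends inside the VOI,
#' accumulated symmetrically (both orderings), then normalizes to
#' probabilities. Directions with no valid voxel pair (thin or single-voxel
#' VOIs) are recorded as `NULL` and excluded from index averaging.
#'
#' @param la Integer gray-level array with NA outside the VOI (see
#'   [extract_ti()] for the composed pipeline).
#' @param directions Direction matrix, by default [texture_directions()].
#' @return An object of class `cm_set`: a list with `matrices` (per-direction
#'   probability matrices or NULL), `n_pairs`, the level extent `L`, and a
#'   `degenerate` flag when no direction has any pair.
#' @export
build_cm <- function(la, directions = texture_directions()) {
  dims <- dim(la)
  L <- max(la, na.rm = TRUE)
  mats <- vector("list", nrow(directions))
  n_pairs <- integer(nrow(directions))
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    rg <- shift_ranges(dims, d)
    if (is.null(rg)) next
    a <- la[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
    b <- la[rg[[1]] + d[1], rg[[2]] + d[2], rg[[3]] + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    av <- a[ok]; bv <- b[ok]
    counts <- tabulate(av + (bv - 1L) * L, nbins = L * L)
    m <- matrix(counts, L, L)
    m <- m + t(m)
    mats[[k]] <- m / sum(m)
    n_pairs[k] <- length(av)
  }
  structure(list(matrices = mats, n_pairs = n_pairs, L = L,
                 degenerate = all(n_pairs == 0L)),
            class = "cm_set")
}

#' Co-occurrence indices: homogeneity, entropy, contrast
#'
#' Per direction, with `p(i, j)` the normalized co-occurrence probabilities:
#' homogeneity `= sum p(i,j) / (1 + |i - j|)`, entropy
#' `= -sum p(i,j) log p(i,j)` over positive cells, contrast
#' `= sum p(i,j) (i - j)^2`. The reported value is the unweighted mean over
#' the directions that have at least one voxel pair.
#'
#' @param cms A `cm_set` from [build_cm()].
#' @param log_base Entropy logarithm base (default 2, i.e. bits).
#' @return Named numeric vector `homogeneity`, `entropy`, `contrast`.
#' @export
cm_indices <- function(cms, log_base = 2) {
  stopifnot(inherits(cms, "cm_set"))
  if (cms$degenerate)
    stop("degenerate co-occurrence matrices: no valid voxel pair in any direction",
         call. = FALSE)
  L <- cms$L
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  w_hom <- 1 / (1 + abs(ii - jj))
  w_con <- (ii - jj)^2
  vals <- vapply(cms$matrices[cms$n_pairs > 0L], function(m) {
    p <- as.vector(m)
    pp <- p[p > 0]
    c(sum(p * w_hom), -sum(pp * log(pp, base = log_base)), sum(p * w_con))
  }, numeric(3))
  out <- rowMeans(vals)
  names(out) <- c("homogeneity", "entropy", "contrast")
  out
}

#' Build per-direction gray-level run-length matrices
#'
#' For each direction the in-mask lattice is decomposed into maximal collinear
#' runs of identical gray level; a run ends at a mask boundary or at a level
#' change. `GRLM_d(i, j)` counts the runs of level `i` and length `j`; the
#' total number of runs `H_d` is the normalization constant of the run-length
#' indices. Every in-mask voxel belongs to exactly one run per direction, so
#' no direction is ever empty for a non-empty VOI.
#'
#' @inheritParams build_cm
#' @return An object of class `grlm_set`: per-direction count matrices
#'   (levels x run lengths), run totals `H`, and the level extent `L`.
#' @export
build_grlm <- function(la, directions = texture_directions()) {
  dims <- dim(la)
  L <- max(la, na.rm = TRUE)
  keep <- !is.na(la)
  coords <- which(keep, arr.ind = TRUE)
  lev <- la[keep]
  off <- max(dims) + 1
  key_base <- 3 * max(dims) + 2
  mats <- vector("list", nrow(directions))
  H <- integer(nrow(directions))
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    c_axis <- which(d != 0)[1]            # canonical directions have d[c_axis] == 1
    m <- coords[, c_axis]
    base <- coords - outer(m, d)          # identical for voxels on one line
    key <- ((base[, 1] + off) * key_base + (base[, 2] + off)) * key_base +
      (base[, 3] + off)
    ord <- order(key, m)
    ks <- key[ord]; ms <- m[ord]; ls <- lev[ord]
    n <- length(ord)
    newrun <- if (n > 1L) {
      c(TRUE, !(diff(ks) == 0 & diff(ms) == 1L & diff(ls) == 0L))
    } else TRUE
    run_id <- cumsum(newrun)
    run_len <- tabulate(run_id)
    run_lev <- ls[newrun]
    jmax <- max(run_len)
    counts <- tabulate(run_lev + (run_len - 1L) * L, nbins = L * jmax)
    mats[[k]] <- matrix(counts, L, jmax)
    H[k] <- length(run_len)
  }
  structure(list(matrices = mats, H = H, L = L), class = "grlm_set")
}

#' Run-length indices: SRE, LRE, RLNU
#'
#' Per direction, with `G(i, j)` the run counts and `H` the total number of
#' runs: short-run emphasis `SRE = (1/H) sum G(i,j) / j^2`, long-run emphasis
#' `LRE = (1/H) sum G(i,j) j^2`, and run-length non-uniformity
#' `RLNU = (1/H) sum_j (sum_i G(i,j))^2`. Values are averaged over directions.
#' For any VOI and direction, `SRE <= 1 <= LRE`; RLNU grows roughly linearly
#' with the voxel count, which is why it never reaches a volume plateau.
#'
#' @param grl A `grlm_set` from [build_grlm()].
#' @return Named numeric vector `sre`, `lre`, `rlnu`.
#' @export
grlm_indices <- function(grl) {
  stopifnot(inherits(grl, "grlm_set"))
  vals <- mapply(function(g, h) {
    j <- seq_len(ncol(g))
    cs <- colSums(g)
    c(sum(cs / j^2) / h, sum(cs * j^2) / h, sum(cs^2) / h)
  }, grl$matrices, grl$H)
  out <- rowMeans(matrix(vals, nrow = 3L))
  names(out) <- c("sre", "lre", "rlnu")
  out
}

#' Build the gray-level zone-length (size-zone) matrix
#'
#' Zones are maximal connected components of equal gray level within the VOI,
#' computed once in full 3D (no direction averaging) with 26-connectivity by
#' default. `GZLM(i, j)` counts the zones of level `i` and size `j` voxels;
#' mass conservation `sum_{i,j} j * Z(i, j) = voxel count` always holds.
#'
#' @param la Integer gray-level array with NA outside the VOI.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `gzlm_set`: the count matrix `Z`
#'   (levels x zone sizes), the zone total `H`, and the level extent `L`.
#' @export
build_gzlm <- function(la, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  dims <- dim(la)
  L <- max(la, na.rm = TRUE)
  keep <- !is.na(la)
  coords <- which(keep, arr.ind = TRUE)
  lev <- la[keep]
  n <- nrow(coords)
  id <- array(NA_integer_, dims)
  id[keep] <- seq_len(n)
  dirs <- texture_directions()
  if (connectivity == 6L) dirs <- dirs[rowSums(abs(dirs)) == 1L, , drop = FALSE]
  edges <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nb <- sweep(coords, 2L, d, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    src <- which(ok)
    nid <- id[nb[ok, , drop = FALSE]]
    good <- !is.na(nid) & lev[src] == lev[nid]
    if (any(good)) edges[[k]] <- cbind(src[good], nid[good])
  }
  edges <- do.call(rbind, edges)
  memb <- if (is.null(edges)) {
    seq_len(n)
  } else {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
    igraph::components(gr)$membership
  }
  sizes <- tabulate(memb)
  ord <- order(memb)
  zone_lev <- lev[ord][!duplicated(memb[ord])]
  jmax <- max(sizes)
  counts <- tabulate(zone_lev + (sizes - 1L) * L, nbins = L * jmax)
  structure(list(Z = matrix(counts, L, jmax), H = length(sizes), L = L),
            class = "gzlm_set")
}

#' Zone indices: LGZE, HGZE
#'
#' With `Z(i, j)` the zone counts and `H` the zone total: low gray-level zone
#' emphasis `LGZE = (1/H) sum Z(i,j) / i^2` and high gray-level zone emphasis
#' `HGZE = (1/H) sum Z(i,j) i^2`. A constant VOI at level `g` gives exactly
#' `LGZE = 1/g^2`, `HGZE = g^2`.
#'
#' @param gz A `gzlm_set` from [build_gzlm()].
#' @return Named numeric vector `lgze`, `hgze`.
#' @export
gzlm_indices <- function(gz) {
  stopifnot(inherits(gz, "gzlm_set"))
  i <- seq_len(gz$L)
  rs <- rowSums(gz$Z)
  c(lgze = sum(rs / i^2) / gz$H, hgze = sum(rs * i^2) / gz$H)
}

ti_index_names <- function() {
  c("homogeneity", "entropy", "contrast", "sre", "lre", "rlnu", "lgze", "hgze")
}

#' Extract the texture-index vector of one VOI
#'
#' Composes the full pipeline for a single VOI: resample the in-mask SUV
#' values according to `spec`, build the co-occurrence, run-length and
#' zone-length matrices, and compute homogeneity, entropy, contrast, SRE,
#' LRE, RLNU, LGZE and HGZE, together with the two conventional indices
#' SUVmax (maximum in-mask SUV, before resampling) and metabolic volume.
#' The result carries full provenance: resampling method and bounds, voxel
#' and clipped-voxel counts, and any segmentation parameters attached to the
#' mask.
#'
#' @param vol A [volume_grid()] in SUV.
#' @param mask A [voi_mask()] congruent with `vol`.
#' @param spec A [resampling_spec()] (default AR, D = 64, bounds 0–20).
#' @param voi_id Optional identifier carried into feature tables.
#' @param log_base Entropy logarithm base.
#' @param connectivity Zone connectivity, 26 (default) or 6.
#' @return An object of class `ti_vector`; `as.data.frame()` turns it into a
#'   one-row feature table with columns `voi_id, method, D, low, high,
#'   homogeneity, entropy, contrast, sre, lre, rlnu, lgze, hgze, suvmax_suv,
#'   mv_ml, n_voxels, n_clipped`.
#' @export
extract_ti <- function(vol, mask, spec = resampling_spec("AR"),
                       voi_id = NA_character_, log_base = 2,
                       connectivity = 26L) {
  stopifnot(inherits(vol, "volume_grid"), inherits(mask, "voi_mask"),
            inherits(spec, "resampling_spec"))
  if (vol$unit != "suv")
    stop("texture indices are defined on SUV volumes; convert with to_suv()",
         call. = FALSE)
  if (!identical(dim(vol$values), dim(mask$mask)))
    stop("mask shape does not match the volume lattice", call. = FALSE)
  suv <- vol$values[mask$mask]
  rv <- resample_voi(suv, spec)
  la <- level_array(rv$levels, mask)
  cm <- build_cm(la)
  cmi <- cm_indices(cm, log_base = log_base)
  gri <- grlm_indices(build_grlm(la))
  gzi <- gzlm_indices(build_gzlm(la, connectivity = connectivity))
  out <- structure(as.list(c(cmi, gri, gzi,
                             suvmax = max(suv),
                             mv = metabolic_volume(mask, vol$spacing))),
                   class = "ti_vector")
  attr(out, "provenance") <- list(
    voi_id = voi_id, method = spec$label, D = spec$D,
    low = if (spec$method == "AR") spec$low else NA_real_,
    high = if (spec$method == "AR") spec$high else NA_real_,
    n_voxels = mask$voxel_count, n_clipped = rv$n_clipped,
    suvmin = rv$source_suvmin, log_base = log_base,
    connectivity = connectivity,
    segmentation = attr(mask, "segmentation"))
  out
}

#' @export
print.ti_vector <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<ti_vector> %s (D = %d), %d voxels, MV = %.3f mL, SUVmax = %.3f\n",
              pr$method, pr$D, pr$n_voxels, x$mv, x$suvmax))
  v <- unlist(x[ti_index_names()])
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.ti_vector <- function(x, ...) {
  pr <- attr(x, "provenance")
  data.frame(voi_id = pr$voi_id, method = pr$method, D = pr$D,
             low = pr$low, high = pr$high,
             homogeneity = x$homogeneity, entropy = x$entropy,
             contrast = x$contrast, sre = x$sre, lre = x$lre, rlnu = x$rlnu,
             lgze = x$lgze, hgze = x$hgze,
             suvmax_suv = x$suvmax, mv_ml = x$mv,
             n_voxels = pr$n_voxels, n_clipped = pr$n_clipped,
             stringsAsFactors = FALSE)
}
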