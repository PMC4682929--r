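#' Volume-of-interest mask
#'
#' A boolean lattice congruent with a [volume_grid()] selecting the voxels
#' analyzed. The study uses three VOI kinds: spheres drawn in the phantom
#' ([sphere_voi()]), adaptive-threshold tumor segmentations
#' ([adaptive_threshold_segment()]) and tumor masks rigidly relocated into
#' reference liver tissue ([relocate_voi()]).
#'
#' @param mask 3D logical array with at least one `TRUE` voxel.
#' @return An object of class `voi_mask` with fields `mask` and `voxel_count`.
#' @export
voi_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3D logical array", call. = FALSE)
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  n <- sum(mask)
  if (n < 1L) stop("empty mask: a VOI must contain at least one voxel", call. = FALSE)
  structure(list(mask = mask, voxel_count = as.integer(n)), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<voi_mask> %d voxels in a %d x %d x %d lattice\n",
              x$voxel_count, d[1], d[2], d[3]))
  invisible(x)
}

#' Spherical VOI centered on a voxel
#'
#' A voxel belongs to the sphere when its center lies within `(diameter - 1)/2`
#' voxel units (Euclidean, inclusive) of the center voxel, so the sphere spans
#' exactly `diameter` voxels across each axis: diameter 1 is the center voxel
#' alone and diameter 3 is the 7-voxel cross (center plus its six face
#' neighbors). Only odd diameters are accepted so the sphere can be centered
#' on a voxel.
#'
#' @param vol A [volume_grid()] (only its lattice shape is used).
#' @param center_voxel Integer (i, j, k) voxel indices of the sphere center.
#' @param diameter_voxels Odd positive integer.
#' @return A [voi_mask()].
#' @export
sphere_voi <- function(vol, center_voxel, diameter_voxels) {
  stopifnot(inherits(vol, "volume_grid"))
  dims <- dim(vol$values)
  center <- check_voxel_triplet(center_voxel, "center_voxel", dims)
  d <- as.integer(diameter_voxels)
  if (length(d) != 1L || is.na(d) || d < 1L || d %% 2L == 0L)
    stop("`diameter_voxels` must be an odd positive integer", call. = FALSE)
  r <- (d - 1L) %/% 2L
  if (any(center - r < 1L) || any(center + r > dims))
    stop("sphere clipped by the volume boundary", call. = FALSE)
  off <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  mask <- array(FALSE, dims)
  mask[sweep(off, 2L, center, "+")] <- TRUE
  voi_mask(mask)
}

# 26-connected flood fill from `seed` over the TRUE voxels of `keep`.
# Returns a logical array of the connected component containing the seed.
flood_fill_26 <- function(keep, seed) {
  dims <- dim(keep)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- array(FALSE, dims)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1L)
  while (nrow(frontier) > 0L) {
    m <- nrow(frontier)
    cand <- cbind(rep(frontier[, 1], each = 26L) + off[, 1],
                  rep(frontier[, 2], each = 26L) + off[, 2],
                  rep(frontier[, 3], each = 26L) + off[, 3])
    ok <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
          cand[, 2] >= 1L & cand[, 2] <= dims[2] &
          cand[, 3] >= 1L & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * dims[1] + (cand[, 3] - 1L) * dims[1] * dims[2]
    new <- keep[lin] & !comp[lin]
    lin <- unique(lin[new])
    if (length(lin) == 0L) break
    comp[lin] <- TRUE
    frontier <- arrayInd(lin, dims)
  }
  comp
}

#' Adaptive-threshold tumor segmentation
#'
#' Contrast-oriented adaptive thresholding: within a local search box around
#' the seed, the lesion core is taken as the voxels above `iso_fraction`
#' (default 70%) of the local maximum SUV; the threshold is
#' `T = beta * mean(core SUV) + background SUV`, with the background estimated
#' as the median SUV in a shell outside the search box. The segmentation is
#' the 26-connected component of voxels with `SUV >= T` containing the seed.
#' A fixed-fraction-of-maximum mode (`mode = "fixed"`, default 40% of the
#' local maximum) is provided as an alternative.
#'
#' The threshold rule, `beta` and the background shell are recorded as
#' attributes of the returned mask so downstream feature tables carry the
#' segmentation provenance.
#'
#' @param vol A [volume_grid()] in SUV.
#' @param seed_voxel Voxel (i, j, k) inside the lesion.
#' @param beta Multiplier of the core mean SUV (default 0.3).
#' @param iso_fraction Core isocontour fraction of the local maximum.
#' @param box_halfwidth Half-width (voxels) of the local search box.
#' @param bg_gap,bg_width Gap and thickness (voxels) of the background shell
#'   outside the search box.
#' @param mode `"adaptive"` (default) or `"fixed"`.
#' @param fixed_fraction Threshold fraction of the local maximum in fixed mode.
#' @param snap_seed Snap the seed to the hottest voxel of the search box
#'   before region growing (default `TRUE`), so a seed placed anywhere in the
#'   lesion — including inside a photopenic necrotic core — grows the same
#'   region from the uptake maximum.
#' @return A [voi_mask()] with segmentation parameters attached as attributes.
#' @export
adaptive_threshold_segment <- function(vol, seed_voxel, beta = 0.3,
                                       iso_fraction = 0.7, box_halfwidth = 12L,
                                       bg_gap = 2L, bg_width = 3L,
                                       mode = c("adaptive", "fixed"),
                                       fixed_fraction = 0.4, snap_seed = TRUE) {
  stopifnot(inherits(vol, "volume_grid"))
  if (vol$unit != "suv") stop("segmentation requires a volume in SUV", call. = FALSE)
  mode <- match.arg(mode)
  v <- vol$values
  dims <- dim(v)
  seed <- check_voxel_triplet(seed_voxel, "seed_voxel", dims)

  box <- lapply(1:3, function(a) seq(max(1L, seed[a] - box_halfwidth),
                                     min(dims[a], seed[a] + box_halfwidth)))
  sub <- v[box[[1]], box[[2]], box[[3]], drop = FALSE]
  local_max <- max(sub)
  if (local_max <= 0)
    stop("empty segmentation: no uptake in the search box around the seed", call. = FALSE)
  if (snap_seed) {
    hot <- which(sub == local_max, arr.ind = TRUE)[1L, ]
    seed <- c(box[[1]][hot[1]], box[[2]][hot[2]], box[[3]][hot[3]])
  }

  if (mode == "adaptive") {
    core_mean <- mean(sub[sub >= iso_fraction * local_max])
    # background: median over the shell between the search box and an outer box
    outer <- lapply(1:3, function(a) seq(max(1L, seed[a] - box_halfwidth - bg_gap - bg_width),
                                         min(dims[a], seed[a] + box_halfwidth + bg_gap + bg_width)))
    osub <- v[outer[[1]], outer[[2]], outer[[3]], drop = FALSE]
    cheb <- pmax(abs(rep(outer[[1]], times = length(outer[[2]]) * length(outer[[3]])) - seed[1]),
                 abs(rep(rep(outer[[2]], each = length(outer[[1]])),
                         times = length(outer[[3]])) - seed[2]),
                 abs(rep(outer[[3]], each = length(outer[[1]]) * length(outer[[2]])) - seed[3]))
    shell_vals <- osub[cheb > box_halfwidth + bg_gap]
    background <- if (length(shell_vals)) stats::median(shell_vals) else 0
    threshold <- beta * core_mean + background
  } else {
    background <- NA_real_
    threshold <- fixed_fraction * local_max
  }

  if (v[seed[1], seed[2], seed[3]] < threshold)
    stop("empty segmentation: seed voxel falls below the adaptive threshold", call. = FALSE)

  comp <- flood_fill_26(v >= threshold, seed)
  idx <- which(comp, arr.ind = TRUE)
  if (any(idx == 1L) || any(sweep(idx, 2L, dims, "-") == 0L))
    warning("segmentation touches the volume border", call. = FALSE)
  out <- voi_mask(comp)
  attr(out, "segmentation") <- list(mode = mode, beta = beta,
                                    iso_fraction = iso_fraction,
                                    fixed_fraction = fixed_fraction,
                                    threshold_suv = threshold,
                                    background_suv = background)
  out
}

#' Rigidly relocate a VOI mask to a new center
#'
#' Translates the mask by an integer number of voxels so that its (rounded)
#' centroid lands on `target_center`. No interpolation is involved, so the
#' voxel count and internal geometry are preserved exactly; this is how a
#' tumor VOI is re-used to sample reference liver tissue.
#'
#' @param mask A [voi_mask()].
#' @param target_center Voxel (i, j, k) for the new mask centroid.
#' @return A [voi_mask()] with identical `voxel_count`.
#' @export
relocate_voi <- function(mask, target_center) {
  stopifnot(inherits(mask, "voi_mask"))
  dims <- dim(mask$mask)
  target <- check_voxel_triplet(target_center, "target_center", dims)
  coords <- which(mask$mask, arr.ind = TRUE)
  centroid <- round(colMeans(coords))
  shift <- target - centroid
  moved <- sweep(coords, 2L, shift, "+")
  if (any(moved < 1L) || any(sweep(moved, 2L, dims, ">")))
    stop("translation clips the mask against the volume boundary", call. = FALSE)
  out <- array(FALSE, dims)
  out[moved] <- TRUE
  voi_mask(out)
}

#' Metabolic volume of a VOI
#'
#' MV = voxel count x dx*dy*dz / 1000, in mL. One voxel at 4 mm isotropic is
#' 0.064 mL; 39 such voxels are 2.496 mL, just under the 2.5 mL inclusion
#' bound applied to segmented tumors.
#'
#' @param mask A [voi_mask()].
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @return Metabolic volume in mL.
#' @export
metabolic_volume <- function(mask, spacing) {
  stopifnot(inherits(mask, "voi_mask"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel dimensions in mm", call. = FALSE)
  mask$voxel_count * prod(spacing) / 1000
}
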