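# Synthetic test-beds: a uniform FDG cylinder with spatially correlated
# reconstruction-like noise, and a two-subtype lung-tumor cohort with a liver
# reference region. These emulate the statistics of reconstructed PET images
# (smooth correlated noise), not the reconstruction itself.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, mean = 0, sd = sigma)
  k / sum(k)
}

# Convolve the columns of a matrix with kernel k, zero padding at the edges.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    s <- t - r - 1L
    src <- seq_len(n) - s
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
  }
  out
}

# Separable 3D Gaussian smoothing; sigma_vox is per-axis in voxel units.
smooth_gaussian_3d <- function(arr, sigma_vox) {
  dims <- dim(arr)
  for (axis in 1:3) {
    if (sigma_vox[axis] <= 0) next
    k <- gaussian_kernel_1d(sigma_vox[axis])
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    m <- matrix(ap, nrow = dims[axis])
    m <- conv_cols(m, k)
    ap <- array(m, dim = dims[perm])
    arr <- aperm(ap, order(perm))
  }
  arr
}

# Smoothed white Gaussian field, rescaled so that (away from edges) the
# voxelwise standard deviation is 1.
correlated_noise_field <- function(dims, sigma_vox) {
  eps <- array(stats::rnorm(prod(dims)), dim = dims)
  if (all(sigma_vox <= 0)) return(eps)
  sm <- smooth_gaussian_3d(eps, sigma_vox)
  shrink <- prod(vapply(sigma_vox, function(s) {
    if (s <= 0) 1 else sqrt(sum(gaussian_kernel_1d(s)^2))
  }, numeric(1)))
  sm / shrink
}

fwhm_to_sigma_vox <- function(fwhm_mm, spacing) {
  (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing
}

#' Specification of the uniform cylinder phantom
#'
#' A water-filled cylinder with uniform FDG concentration, imaged on a 4 mm
#' isotropic grid. The reconstructed-image statistics are emulated as
#' Gaussian white noise (standard deviation `noise_sd_frac` of the mean)
#' convolved with a Gaussian point-spread function of `psf_fwhm` mm FWHM, so
#' the only texture present is the spatially correlated noise of the signal.
#'
#' @param cylinder_height,cylinder_diameter Cylinder size in mm.
#' @param voxel Isotropic voxel size in mm.
#' @param mean_suv Uniform SUV level inside the cylinder.
#' @param noise_sd_frac White-noise standard deviation as a fraction of
#'   `mean_suv` (before smoothing).
#' @param psf_fwhm Gaussian PSF full width at half maximum, mm.
#' @param margin_voxels Lattice margin around the cylinder.
#' @param seed RNG seed making the simulation reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_height = 200, cylinder_diameter = 160,
                         voxel = 4, mean_suv = 3, noise_sd_frac = 0.15,
                         psf_fwhm = 7, margin_voxels = 3L, seed = 1L) {
  stopifnot(cylinder_height > 0, cylinder_diameter > 0, voxel > 0,
            mean_suv > 0, noise_sd_frac >= 0, psf_fwhm >= 0, margin_voxels >= 2L)
  structure(list(cylinder_height = cylinder_height,
                 cylinder_diameter = cylinder_diameter, voxel = voxel,
                 mean_suv = mean_suv, noise_sd_frac = noise_sd_frac,
                 psf_fwhm = psf_fwhm, margin_voxels = as.integer(margin_voxels),
                 seed = seed),
            class = "phantom_spec")
}

phantom_dims <- function(spec) {
  nxy <- ceiling(spec$cylinder_diameter / spec$voxel) + 2L * spec$margin_voxels
  nz <- ceiling(spec$cylinder_height / spec$voxel) + 2L * spec$margin_voxels
  c(nxy, nxy, nz)
}

#' Simulate the uniform FDG phantom
#'
#' The cylinder interior is `mean_suv` plus spatially correlated zero-mean
#' noise (white Gaussian noise of sd `noise_sd_frac * mean_suv`, smoothed by
#' the PSF and renormalized to that sd); the exterior is zero. With
#' `noise_sd_frac = 0` the interior is exactly uniform; with `psf_fwhm = 0`
#' the noise is voxelwise independent. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A [volume_grid()] in SUV.
#' @export
simulate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- phantom_dims(spec)
  v <- spec$voxel
  cx <- dims * v / 2
  x <- (seq_len(dims[1]) - 0.5) * v
  y <- (seq_len(dims[2]) - 0.5) * v
  z <- (seq_len(dims[3]) - 0.5) * v
  rad2 <- outer((x - cx[1])^2, (y - cx[2])^2, "+")
  inside <- outer(rad2 <= (spec$cylinder_diameter / 2)^2,
                  abs(z - cx[3]) <= spec$cylinder_height / 2, "&")
  vals <- array(0, dims)
  vals[inside] <- spec$mean_suv
  if (spec$noise_sd_frac > 0) {
    sigma_vox <- fwhm_to_sigma_vox(spec$psf_fwhm, rep(v, 3))
    noise <- with_seed(spec$seed, correlated_noise_field(dims, sigma_vox))
    vals <- vals + spec$mean_suv * spec$noise_sd_frac * noise * inside
  }
  vals[vals < 0] <- 0
  volume_grid(vals, spacing = rep(v, 3), unit = "suv")
}

#' Default sphere positions inside the phantom
#'
#' Five centers — the cylinder axis center plus two axial and two radial
#' offsets — all placed so that a sphere of `max_diameter` voxels stays at
#' least two voxels away from the cylinder wall.
#'
#' @param spec A [phantom_spec()].
#' @param n_positions Number of centers (up to 7 candidates).
#' @param max_diameter Largest sphere diameter (voxels) the positions must
#'   accommodate.
#' @return An integer matrix, one (i, j, k) center per row.
#' @export
phantom_sphere_centers <- function(spec = phantom_spec(), n_positions = 5L,
                                   max_diameter = 17L) {
  dims <- phantom_dims(spec)
  c0 <- round((dims + 1) / 2)
  r <- (max_diameter - 1) %/% 2
  rad_vox <- floor(spec$cylinder_diameter / 2 / spec$voxel)
  hz_vox <- floor(spec$cylinder_height / 2 / spec$voxel)
  dr <- rad_vox - r - 2L
  dz <- hz_vox - r - 2L
  if (dr < 1L || dz < 1L)
    stop("phantom too small for the requested sphere diameter", call. = FALSE)
  cand <- rbind(c0,
                c0 + c(0L, 0L, dz), c0 - c(0L, 0L, dz),
                c0 + c(dr, 0L, 0L), c0 - c(dr, 0L, 0L),
                c0 + c(0L, dr, 0L), c0 - c(0L, dr, 0L))
  if (n_positions > nrow(cand))
    stop("at most 7 default positions are available", call. = FALSE)
  cand <- cand[seq_len(n_positions), , drop = FALSE]
  storage.mode(cand) <- "integer"
  rownames(cand) <- paste0("pos", seq_len(nrow(cand)))
  cand
}

#' Specification of the synthetic NSCLC cohort
#'
#' Each synthetic patient volume contains a low-uptake body background, a
#' liver reference block with mild correlated noise, and one lung tumor: a
#' smooth radial SUV profile rising to a subtype-drawn peak, multiplied by
#' correlated noise. Squamous-like tumors draw a higher peak and, with
#' probability `core_prob`, carry an interior necrotic core at
#' `core_frac` of the peak — the mechanism by which squamous heterogeneity
#' exceeds adenocarcinoma heterogeneity. Defaults give 28 adeno-like and 13
#' squamous-like patients.
#'
#' @param n_adeno,n_squamous Group sizes (>= 2, or 0 for an empty group).
#' @param grid_dim Lattice dimensions of each patient volume.
#' @param voxel Isotropic voxel size in mm.
#' @param adeno_peak,squamous_peak Peak-SUV ranges (uniform draw).
#' @param adeno_radius,squamous_radius Tumor radius ranges in mm.
#' @param core_prob Probability that a squamous tumor carries a necrotic core.
#' @param core_frac Core SUV as a fraction of the tumor peak.
#' @param core_radius_frac Core radius as a fraction of the tumor radius.
#' @param liver_suv Mean liver SUV.
#' @param liver_noise_frac,tumor_noise_frac,background_noise_frac Relative
#'   (multiplicative) noise levels per tissue.
#' @param liver_texture_range Fractional dynamic range of the smooth
#'   parenchymal uptake variation of the liver (vasculature, lobular
#'   inhomogeneity, partial-volume at PET resolution): 0.5 means local liver
#'   uptake spans evenly from 50% to 100% of `liver_suv`. The spatial field
#'   is a correlated Gaussian field transformed through its own CDF, so the
#'   stated range is filled uniformly.
#' @param liver_texture_fwhm Correlation length (mm FWHM) of that field.
#' @param background_suv Mean body-background SUV.
#' @param psf_fwhm Gaussian PSF FWHM in mm shared by all noise fields.
#' @param noise_white_share Share (amplitude mixing weight in `[0, 1]`) of the
#'   reconstruction noise that is voxelwise uncorrelated; the remainder is
#'   smoothed by the PSF. Iterative reconstruction leaves part of the voxel
#'   noise uncorrelated, and this component dominates the fine-scale
#'   gray-level transitions that min-max resampled indices see.
#' @param edge_width_mm Width of the sigmoid tumor edge (PSF-blurred margin).
#' @param delay_mean,delay_sd,delay_range Injection-to-scan delay model
#'   (truncated normal, minutes).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_adeno = 28L, n_squamous = 13L,
                        grid_dim = c(56L, 56L, 56L), voxel = 4,
                        adeno_peak = c(4, 10), squamous_peak = c(6, 16),
                        adeno_radius = c(10, 24), squamous_radius = c(11, 26),
                        core_prob = 0.7, core_frac = 0.25,
                        core_radius_frac = 0.35,
                        liver_suv = 2.2, liver_noise_frac = 0.10,
                        liver_texture_range = 0.5,
                        liver_texture_fwhm = 12,
                        tumor_noise_frac = 0.10, background_suv = 0.5,
                        background_noise_frac = 0.10,
                        psf_fwhm = 7, noise_white_share = 0.6,
                        edge_width_mm = 1.2,
                        delay_mean = 75, delay_sd = 9,
                        delay_range = c(60, 90), seed = 1L) {
  stopifnot(n_adeno >= 0, n_squamous >= 0,
            n_adeno == 0 || n_adeno >= 2, n_squamous == 0 || n_squamous >= 2,
            all(adeno_peak > 0), diff(adeno_peak) >= 0,
            all(squamous_peak > 0), diff(squamous_peak) >= 0,
            all(adeno_radius > 0), all(squamous_radius > 0),
            core_prob >= 0, core_prob <= 1, core_frac > 0, core_frac < 1,
            liver_suv > 0, background_suv >= 0, voxel > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

simulate_patient <- function(spec, subtype) {
  dims <- spec$grid_dim
  v <- spec$voxel
  peak_rng <- if (subtype == "adeno") spec$adeno_peak else spec$squamous_peak
  rad_rng <- if (subtype == "adeno") spec$adeno_radius else spec$squamous_radius
  peak <- stats::runif(1, peak_rng[1], peak_rng[2])
  radius <- stats::runif(1, rad_rng[1], rad_rng[2])
  has_core <- subtype == "squamous" && stats::runif(1) < spec$core_prob
  # truncated-normal injection-to-scan delay
  lo <- stats::pnorm(spec$delay_range[1], spec$delay_mean, spec$delay_sd)
  hi <- stats::pnorm(spec$delay_range[2], spec$delay_mean, spec$delay_sd)
  delay <- stats::qnorm(stats::runif(1, lo, hi), spec$delay_mean, spec$delay_sd)

  liver_center <- as.integer(c(14L, 14L, round(dims[3] / 2)))
  liver_half <- 10L
  tumor_center <- as.integer(c(dims[1] - 16L, dims[2] - 16L, round(dims[3] / 2)) +
                               sample(-2:2, 3L, replace = TRUE))

  x <- (seq_len(dims[1]) - 0.5) * v
  y <- (seq_len(dims[2]) - 0.5) * v
  z <- (seq_len(dims[3]) - 0.5) * v
  tc <- (tumor_center - 0.5) * v
  rho <- sqrt(outer(outer((x - tc[1])^2, (y - tc[2])^2, "+"), (z - tc[3])^2, "+"))
  g <- stats::plogis(-(rho - radius) / spec$edge_width_mm)
  necro <- if (has_core) {
    spec$core_frac + (1 - spec$core_frac) *
      stats::plogis((rho - spec$core_radius_frac * radius) / spec$edge_width_mm)
  } else 1

  base <- array(spec$background_suv, dims)
  lx <- pmax(1L, liver_center[1] - liver_half):pmin(dims[1], liver_center[1] + liver_half)
  ly <- pmax(1L, liver_center[2] - liver_half):pmin(dims[2], liver_center[2] + liver_half)
  lz <- pmax(1L, liver_center[3] - liver_half):pmin(dims[3], liver_center[3] + liver_half)
  # smooth parenchymal uptake variation with an evenly filled dynamic range:
  # a correlated Gaussian field pushed through its CDF has a uniform marginal
  if (spec$liver_texture_range > 0) {
    sigl <- fwhm_to_sigma_vox(spec$liver_texture_fwhm, rep(v, 3))
    gfield <- correlated_noise_field(dims, sigl)
    liver_tex <- 1 - spec$liver_texture_range * stats::pnorm(gfield[lx, ly, lz])
    base[lx, ly, lz] <- spec$liver_suv * liver_tex
  } else {
    base[lx, ly, lz] <- spec$liver_suv
  }
  base <- base * (1 - g) + peak * necro * g

  frac <- array(spec$background_noise_frac, dims)
  frac[lx, ly, lz] <- spec$liver_noise_frac
  frac[rho <= 1.2 * radius] <- spec$tumor_noise_frac
  sigma_vox <- fwhm_to_sigma_vox(spec$psf_fwhm, rep(v, 3))
  a <- spec$noise_white_share
  u <- sqrt(1 - a^2) * correlated_noise_field(dims, sigma_vox) +
    a * array(stats::rnorm(prod(dims)), dim = dims)
  vals <- base * (1 + frac * u)
  vals[vals < 0] <- 0

  list(vol = volume_grid(vals, spacing = rep(v, 3), unit = "suv"),
       peak_suv = peak, radius_mm = radius, has_core = has_core,
       delay_min = delay, tumor_center = tumor_center,
       liver_center = liver_center)
}

#' Simulate the synthetic NSCLC cohort
#'
#' Generates one volume per patient plus a cohort ledger recording the
#' planted truth: subtype, injection-to-scan delay, tumor peak SUV, radius,
#' necrotic-core flag, geometric tumor volume, and the tumor and liver
#' center voxels used downstream for segmentation and VOI relocation.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `volumes` (list of [volume_grid()]) and `ledger`
#'   (data frame, one row per patient).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subtypes <- c(rep("adeno", spec$n_adeno), rep("squamous", spec$n_squamous))
  n <- length(subtypes)
  if (n == 0L) {
    return(list(volumes = list(),
                ledger = data.frame(patient_id = character(0),
                                    subtype = character(0),
                                    delay_min = numeric(0), mv_ml = numeric(0),
                                    peak_suv = numeric(0), radius_mm = numeric(0),
                                    has_core = logical(0))))
  }
  with_seed(spec$seed, {
    pats <- lapply(subtypes, function(st) simulate_patient(spec, st))
    ledger <- data.frame(
      patient_id = sprintf("P%02d", seq_len(n)),
      subtype = subtypes,
      delay_min = vapply(pats, `[[`, numeric(1), "delay_min"),
      mv_ml = vapply(pats, function(p) 4 / 3 * pi * p$radius_mm^3 / 1000, numeric(1)),
      peak_suv = vapply(pats, `[[`, numeric(1), "peak_suv"),
      radius_mm = vapply(pats, `[[`, numeric(1), "radius_mm"),
      has_core = vapply(pats, `[[`, logical(1), "has_core"),
      stringsAsFactors = FALSE)
    centers <- t(vapply(pats, `[[`, integer(3), "tumor_center"))
    lcenters <- t(vapply(pats, `[[`, integer(3), "liver_center"))
    ledger$tumor_ci <- centers[, 1]; ledger$tumor_cj <- centers[, 2]
    ledger$tumor_ck <- centers[, 3]
    ledger$liver_ci <- lcenters[, 1]; ledger$liver_cj <- lcenters[, 2]
    ledger$liver_ck <- lcenters[, 3]
    list(volumes = lapply(pats, `[[`, "vol"), ledger = ledger)
  })
}

#' Apply the cohort exclusion filters
#'
#' Retains patients whose injection-to-scan delay lies inside the closed
#' `delay_range` and whose metabolic volume after segmentation is at least
#' `mv_min`, applied in that order, and tallies the exclusions per criterion.
#'
#' @param ledger Cohort ledger data frame with columns `delay_min` and `mv_ml`.
#' @param delay_range Closed admissible delay interval in minutes.
#' @param mv_min Minimum metabolic volume in mL.
#' @return A list: `ledger` (retained rows), `tally` (data frame with one row
#'   per criterion in application order) and `kept` (logical index into the
#'   input).
#' @export
apply_exclusions <- function(ledger, delay_range = c(60, 90), mv_min = 2.5) {
  stopifnot(is.data.frame(ledger),
            all(c("delay_min", "mv_ml") %in% names(ledger)))
  ok_delay <- ledger$delay_min >= delay_range[1] & ledger$delay_min <= delay_range[2]
  ok_mv <- ledger$mv_ml >= mv_min
  kept <- ok_delay & ok_mv
  tally <- data.frame(
    criterion = c("delay_out_of_range", "mv_below_min"),
    n_excluded = c(sum(!ok_delay), sum(ok_delay & !ok_mv)))
  list(ledger = ledger[kept, , drop = FALSE], tally = tally, kept = kept)
}
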