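#' Gray-level resampling specification
#'
#' Texture matrices are computed on discretized gray levels, not raw SUV.
#' Two schemes are supported:
#'
#' * **RR** (relative resampling): levels are spread between the VOI minimum
#'   and maximum, `level(x) = round(D * (I(x) - SUVmin) / (SUVmax - SUVmin)) + 1`.
#' * **AR** (absolute resampling): levels are spread between fixed SUV bounds
#'   identical for every VOI, `level(x) = round(D * (I(x) - low) / (high - low)) + 1`
#'   after clipping `I(x)` into `[low, high]`.
#'
#' Both maps use half-up rounding and a +1 shift so levels occupy `1..D+1`
#' (the raw rounding yields 0, which would make the 1/i^2 weight of low
#' gray-level emphasis undefined). `D = 64` and AR bounds 0–20 SUV are the
#' defaults; AR high bounds 15 and 25 are the robustness presets.
#'
#' @param method `"RR"` or `"AR"`.
#' @param D Number of discretization steps (integer >= 2, default 64).
#' @param low,high Fixed SUV bounds (AR only; default 0 and 20).
#' @return An object of class `resampling_spec` with a `label` field
#'   (`"RR"`, `"AR20"`, ...) used in feature tables.
#' @seealso [resampling_preset()], [resample_rr()], [resample_ar()]
#' @export
resampling_spec <- function(method = c("RR", "AR"), D = 64L, low = 0, high = 20) {
  method <- match.arg(toupper(method), c("RR", "AR"))
  D <- as.integer(D)
  if (is.na(D) || D < 2L) stop("`D` must be an integer >= 2", call. = FALSE)
  if (!is.finite(low) || !is.finite(high) || high <= low)
    stop("resampling bounds must satisfy high > low", call. = FALSE)
  label <- if (method == "RR") "RR" else sprintf("AR%g", high)
  structure(list(method = method, D = D, low = low, high = high, label = label),
            class = "resampling_spec")
}

#' @export
print.resampling_spec <- function(x, ...) {
  if (x$method == "RR") {
    cat(sprintf("<resampling_spec> RR (min-max), D = %d\n", x$D))
  } else {
    cat(sprintf("<resampling_spec> AR, D = %d, bounds [%g, %g] SUV (bin width %.4g SUV)\n",
                x$D, x$low, x$high, ar_bin_width(x)))
  }
  invisible(x)
}

#' Named resampling presets
#'
#' `"rr"` is min–max relative resampling; `"ar15"`, `"ar20"`, `"ar25"` are
#' absolute resampling with low bound 0 and high bound 15, 20 or 25 SUV, all
#' with D = 64.
#'
#' @param name Preset name (case-insensitive).
#' @param D Number of discretization steps.
#' @return A [resampling_spec()].
#' @export
resampling_preset <- function(name, D = 64L) {
  name <- tolower(name)
  switch(name,
         rr   = resampling_spec("RR", D),
         ar15 = resampling_spec("AR", D, 0, 15),
         ar20 = resampling_spec("AR", D, 0, 20),
         ar25 = resampling_spec("AR", D, 0, 25),
         stop(sprintf("unknown resampling preset '%s'", name), call. = FALSE))
}

#' Bin width of an absolute resampling spec
#'
#' `(high - low) / D` in SUV units: 20/64 = 0.3125, i.e. approximately 0.3 SUV
#' at the defaults.
#'
#' @param spec A [resampling_spec()] with `method == "AR"`.
#' @return Bin width in SUV.
#' @export
ar_bin_width <- function(spec) {
  stopifnot(inherits(spec, "resampling_spec"))
  if (spec$method != "AR") stop("bin width is defined for AR specs only", call. = FALSE)
  (spec$high - spec$low) / spec$D
}

new_resampled_voi <- function(levels, spec, suvmin, suvmax, n_clipped) {
  structure(list(levels = as.integer(levels), spec = spec,
                 source_suvmin = suvmin, source_suvmax = suvmax,
                 n_clipped = as.integer(n_clipped)),
            class = "resampled_voi")
}

#' Relative (min–max) resampling of in-mask SUV values
#'
#' `level(x) = round(D * (I(x) - SUVmin) / (SUVmax - SUVmin)) + 1`, half-up
#' rounding: the VOI minimum maps to level 1 and the maximum to level D + 1.
#' A constant region (SUVmax = SUVmin) maps entirely to level 1. Because the
#' map is invariant under any strictly increasing affine transform of the
#' intensities, RR-based texture indices carry no information about the SUV
#' scale of the VOI.
#'
#' @param values Numeric vector of in-mask SUV values (>= 1 voxel).
#' @param D Number of discretization steps.
#' @return An object of class `resampled_voi` with integer `levels` in
#'   `1..D+1`, the spec, and the source SUV range.
#' @export
resample_rr <- function(values, D = 64L) {
  if (length(values) < 1L) stop("empty input: no voxels to resample", call. = FALSE)
  spec <- resampling_spec("RR", D)
  smin <- min(values); smax <- max(values)
  lev <- if (smax > smin) {
    round_half_up(spec$D * (values - smin) / (smax - smin)) + 1L
  } else {
    rep(1L, length(values))
  }
  new_resampled_voi(lev, spec, smin, smax, 0L)
}

#' Absolute (fixed-bound) resampling of in-mask SUV values
#'
#' `level(x) = round(D * (clip(I(x)) - low) / (high - low)) + 1` with
#' `clip()` confining values to `[low, high]`: `I = low` maps to level 1,
#' `I = high` to level D + 1, and values outside the bounds are clipped to the
#' boundary levels (the number of clipped voxels is reported). The bounds are
#' the same for every VOI, so the levels retain the absolute SUV scale.
#'
#' @param values Numeric vector of in-mask SUV values (>= 1 voxel).
#' @param D Number of discretization steps.
#' @param low,high Fixed SUV bounds.
#' @return An object of class `resampled_voi`; `n_clipped` counts voxels
#'   outside `[low, high]`.
#' @export
resample_ar <- function(values, D = 64L, low = 0, high = 20) {
  if (length(values) < 1L) stop("empty input: no voxels to resample", call. = FALSE)
  spec <- resampling_spec("AR", D, low, high)
  n_clipped <- sum(values < low | values > high)
  cl <- pmin(pmax(values, low), high)
  lev <- round_half_up(spec$D * (cl - low) / (high - low)) + 1L
  new_resampled_voi(lev, spec, min(values), max(values), n_clipped)
}

#' Resample values according to a spec
#'
#' Dispatches to [resample_rr()] or [resample_ar()].
#'
#' @param values Numeric vector of in-mask SUV values.
#' @param spec A [resampling_spec()].
#' @return An object of class `resampled_voi`.
#' @export
resample_voi <- function(values, spec) {
  stopifnot(inherits(spec, "resampling_spec"))
  if (spec$method == "RR") resample_rr(values, spec$D)
  else resample_ar(values, spec$D, spec$low, spec$high)
}

#' Fixed-bin-width resampling (convenience alias)
#'
#' Discretizing with a fixed bin width `w` and `D` levels starting at 0 is the
#' same map as absolute resampling with bounds `[0, w * D]`: a 0.5 SUV bin
#' width with 64 levels is AR with high bound 32 SUV.
#'
#' @param values Numeric vector of in-mask SUV values.
#' @param bin_width Bin width in SUV.
#' @param D Number of discretization steps.
#' @return An object of class `resampled_voi`.
#' @export
resample_fixed_width <- function(values, bin_width = 0.5, D = 64L) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a positive SUV width", call. = FALSE)
  resample_ar(values, D = D, low = 0, high = bin_width * D)
}
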