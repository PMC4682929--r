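#' 3D PET volume with voxel spacing and an intensity-unit tag
#'
#' A `volume_grid` holds a 3D scalar lattice of non-negative, finite voxel
#' values together with the voxel spacing in mm and a tag saying whether the
#' values are activity concentration (kBq/mL) or body-weight standardized
#' uptake values (SUV).
#'
#' @param values 3D numeric array; all entries finite and >= 0.
#' @param spacing Numeric length-3, voxel dimensions (dx, dy, dz) in mm.
#' @param unit `"suv"` or `"activity"` (kBq/mL).
#' @return An object of class `volume_grid` with fields `values`, `spacing`
#'   and `unit`.
#' @examples
#' v <- volume_grid(array(1, c(4, 4, 4)), spacing = c(4, 4, 4), unit = "suv")
#' @export
volume_grid <- function(values, spacing = c(4, 4, 4), unit = c("suv", "activity")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("PET activity/SUV values must be >= 0", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel dimensions in mm", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, unit = unit),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, unit = %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Acquisition metadata for SUV conversion
#'
#' Holds the quantities needed to convert activity concentration into
#' body-weight-normalized SUV: injected activity, patient body weight and an
#' optional decay interval between the activity assay and scan time.
#'
#' @param injected_activity_mbq Injected activity in MBq (> 0).
#' @param body_weight_kg Body weight in kg (> 0).
#' @param decay_interval_min Minutes elapsed between the reference time of
#'   `injected_activity_mbq` and scan time; 0 (the default) means the stated
#'   activity is already decay-corrected to scan time.
#' @param half_life_min Isotope half-life in minutes; default 109.77 (18F).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_mbq, body_weight_kg,
                             decay_interval_min = 0, half_life_min = 109.77) {
  if (!is.numeric(injected_activity_mbq) || length(injected_activity_mbq) != 1L ||
      !is.finite(injected_activity_mbq) || injected_activity_mbq <= 0)
    stop("invalid metadata: `injected_activity_mbq` must be a positive number", call. = FALSE)
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("invalid metadata: `body_weight_kg` must be a positive number", call. = FALSE)
  if (!is.numeric(decay_interval_min) || decay_interval_min < 0)
    stop("invalid metadata: `decay_interval_min` must be >= 0", call. = FALSE)
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("invalid metadata: `half_life_min` must be > 0", call. = FALSE)
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 body_weight_kg = body_weight_kg,
                 decay_interval_min = decay_interval_min,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' SUV(x) = C(x) \[kBq/mL\] * weight \[kg\] / (A \[MBq\] * 2^(-t/T)), where A is
#' the injected activity, t the decay interval and T the isotope half-life.
#' The unit factors cancel under the conventional 1 g/mL tissue density
#' (kg -> g and MBq -> kBq both contribute a factor 1000), so a voxel at
#' 3.5 kBq/mL with 70 kg and 245 MBq at scan time has SUV exactly 1.
#'
#' @param vol A [volume_grid()] with `unit == "activity"` (kBq/mL).
#' @param meta An [acquisition_meta()].
#' @return A [volume_grid()] in SUV with the same shape and spacing.
#' @export
to_suv <- function(vol, meta) {
  stopifnot(inherits(vol, "volume_grid"), inherits(meta, "acquisition_meta"))
  if (vol$unit != "activity")
    stop("`vol` must be in activity units (kBq/mL) before SUV conversion", call. = FALSE)
  activity_at_scan <- meta$injected_activity_mbq *
    2^(-meta$decay_interval_min / meta$half_life_min)
  suv <- vol$values * meta$body_weight_kg / activity_at_scan
  volume_grid(suv, spacing = vol$spacing, unit = "suv")
}

#' Read / write a 3D volume as NIfTI-1
#'
#' `read_volume()` loads a single-channel 3D NIfTI-1 image into a
#' [volume_grid()]; `write_volume()` stores one (double precision, so the
#' round trip preserves values exactly). Voxel spacing is taken from, and
#' written to, the NIfTI `pixdim` header field.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param unit Unit tag to attach to the values read; NIfTI has no SUV unit
#'   code, so the caller must say what the file holds.
#' @return `read_volume()` a [volume_grid()]; `write_volume()` the path,
#'   invisibly.
#' @export
read_volume <- function(path, unit = c("suv", "activity")) {
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions", length(d)), call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("voxel spacing metadata missing or invalid in NIfTI header", call. = FALSE)
  vals <- array(as.numeric(img), dim = d)
  vals[vals < 0 & vals > -1e-6] <- 0  # storage round-off only
  volume_grid(vals, spacing = sp[1:3], unit = unit)
}

#' @param vol A [volume_grid()] to write.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  vals <- vol$values
  attr(vals, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "double"), path)
  invisible(path)
}

#' Read / write a binary VOI mask as a NIfTI-1 label image
#'
#' Masks are stored as 0/1 uint8 label volumes aligned with their parent
#' [volume_grid()].
#'
#' @param path File path.
#' @return `read_mask()` a [voi_mask()]; `write_mask()` the path, invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D label image, got %d dimensions", length(d)), call. = FALSE)
  vals <- array(as.numeric(img), dim = d)
  if (!all(vals %in% c(0, 1)))
    stop("mask image must contain only 0/1 labels", call. = FALSE)
  voi_mask(array(vals == 1, dim = d))
}

#' @param mask A [voi_mask()] to write.
#' @param spacing Voxel spacing in mm recorded in the header.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path, spacing = c(4, 4, 4)) {
  stopifnot(inherits(mask, "voi_mask"))
  lab <- array(0L, dim = dim(mask$mask))
  lab[mask$mask] <- 1L
  attr(lab, "pixdim") <- as.numeric(spacing)
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "uint8"), path)
  invisible(path)
}
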