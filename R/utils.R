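# Internal helpers shared across modules.

# Half-up rounding. Gray-level discretization must not depend on the
# platform's banker's rounding: round(0.5) here is always 1.
round_half_up <- function(x) floor(x + 0.5)

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulators are deterministic without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Bounding box of TRUE (or non-NA) entries of a 3D array, as a list of three
# index ranges.
bbox_ranges <- function(keep) {
  idx <- which(keep, arr.ind = TRUE)
  lapply(1:3, function(a) seq(min(idx[, a]), max(idx[, a])))
}

check_voxel_triplet <- function(x, name, dims = NULL) {
  x <- as.integer(round(x))
  if (length(x) != 3L || anyNA(x))
    stop(sprintf("`%s` must be three voxel indices (i, j, k)", name), call. = FALSE)
  if (!is.null(dims) && (any(x < 1L) || any(x > dims)))
    stop(sprintf("`%s` lies outside the volume lattice", name), call. = FALSE)
  x
}
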