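#' Electron-density map
#'
#' A periodic real-valued density (e/A^3) sampled on a regular grid over the
#' unit cell. Voxel (i,j,k) (1-based) sits at fractional coordinates
#' ((i-1)/n1, (j-1)/n2, (k-1)/n3).
#'
#' @param values 3-D numeric array.
#' @param cell A [unit_cell()].
#' @return Object of class `density_map` with elements `values` and `cell`.
#' @export
density_map <- function(values, cell) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (!is.numeric(values)) stop("density must be real-valued")
  structure(list(values = values, cell = cell), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density map  %dx%dx%d  range [%.4g, %.4g] e/A^3  mean %.4g\n",
              d[1], d[2], d[3], min(x$values), max(x$values), mean(x$values)))
  print(x$cell)
  invisible(x)
}

#' Voxel volume of a map (A^3)
#' @param map A [density_map()].
#' @export
voxel_volume <- function(map) {
  cell_volume(map$cell) / prod(dim(map$values))
}

#' Protein/solvent mask
#'
#' Boolean per-voxel support (TRUE = protein) on the same grid as a
#' [density_map()].
#'
#' @param values 3-D logical array.
#' @param cell A [unit_cell()].
#' @export
mask_grid <- function(values, cell) {
  if (length(dim(values)) != 3 || !is.logical(values))
    stop("mask values must be a 3-D logical array")
  structure(list(values = values, cell = cell), class = "mask_grid")
}

#' Fraction of voxels inside the protein mask
#' @param mask A [mask_grid()].
#' @export
protein_fraction <- function(mask) mean(mask$values)

#' @export
print.mask_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("mask  %dx%dx%d  protein fraction %.4f\n",
              d[1], d[2], d[3], protein_fraction(x)))
  invisible(x)
}

#' Complex structure-factor set
#'
#' One record per unique reflection on the standard Friedel hemisphere
#' (density is real, so F(-h) = Conj(F(h)) is implied). F(000) is excluded.
#'
#' @param hkl n x 3 matrix or data frame of Miller indices.
#' @param f Complex structure factors (electrons).
#' @param cell A [unit_cell()].
#' @param d Optional precomputed resolutions; computed from `hkl` if missing.
#' @return A data frame of class `sf_set` with columns h,k,l,f,d and a
#'   `cell` attribute.
#' @export
sf_set <- function(hkl, f, cell, d = NULL) {
  hkl <- as.matrix(hkl)
  stopifnot(ncol(hkl) == 3, nrow(hkl) == length(f))
  if (!all(hemisphere_side(hkl[, 1], hkl[, 2], hkl[, 3])))
    stop("sf_set indices must lie on the standard hemisphere (no Friedel duplicates, no 000)")
  if (is.null(d)) d <- resolution_of(hkl, cell)
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]), d = d)
  out$f <- as.complex(f)
  attr(out, "cell") <- cell
  class(out) <- c("sf_set", "data.frame")
  out
}

#' Amplitudes of a structure-factor set
#' @param sf An [sf_set()].
#' @export
sf_amplitude <- function(sf) Mod(sf$f)

#' Phases of a structure-factor set, degrees in [0, 360)
#' @param sf An [sf_set()].
#' @export
sf_phase <- function(sf) (Arg(sf$f) * 180 / pi) %% 360

#' Observed-reflection set
#'
#' Unique reflections on the standard hemisphere with observed amplitudes and
#' per-reflection status: `observed`, `missing` (inside the resolution sphere
#' but not measured), `free` (held out for the free R factor) or
#' `low_res_replaced` (measured but replaced by calculated values during the
#' iteration, as done for the lowest-resolution shell).
#'
#' @param hkl n x 3 matrix/data frame of Miller indices.
#' @param f_obs Observed amplitudes (NA where missing).
#' @param cell A [unit_cell()].
#' @param d_min Resolution cutoff (A); all reflections must have d >= d_min.
#' @param sigma Optional amplitude sigmas (NA allowed).
#' @param status Character vector; defaults to `observed` where `f_obs` is
#'   present and `missing` elsewhere.
#' @param phase Optional phase column (degrees) carried through symmetry
#'   expansion; not used by the engine.
#' @return Data frame of class `refl_set` with attributes `cell`, `d_min`.
#' @export
reflection_set <- function(hkl, f_obs, cell, d_min, sigma = NA_real_,
                           status = NULL, phase = NULL) {
  hkl <- as.matrix(hkl)
  n <- nrow(hkl)
  if (!all(hemisphere_side(hkl[, 1], hkl[, 2], hkl[, 3])))
    stop("reflection indices must lie on the standard hemisphere")
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key))
    stop("duplicate hkl: ", key[duplicated(key)][1])
  d <- resolution_of(hkl, cell)
  if (any(d < d_min - 1e-9))
    stop("reflections beyond the d_min cutoff present")
  if (is.null(status))
    status <- ifelse(is.na(f_obs), "missing", "observed")
  status <- match.arg(status, c("observed", "missing", "free", "low_res_replaced"),
                      several.ok = TRUE)
  if (length(status) == 1) status <- rep(status, n)
  bad <- status == "observed" & is.na(f_obs)
  if (any(bad)) stop("status 'observed' requires a present f_obs")
  if (any(status == "missing" & !is.na(f_obs)))
    stop("status 'missing' requires an absent f_obs")
  if (any(f_obs < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]),
                    f_obs = as.numeric(f_obs),
                    sigma = rep_len(as.numeric(sigma), n),
                    d = d, status = status, stringsAsFactors = FALSE)
  if (!is.null(phase)) out$phase <- as.numeric(phase)
  attr(out, "cell") <- cell
  attr(out, "d_min") <- d_min
  class(out) <- c("refl_set", "data.frame")
  out
}

#' @export
print.refl_set <- function(x, ...) {
  cat(sprintf("reflection set  %d unique hkl  d_min %.2f A\n",
              nrow(x), attr(x, "d_min")))
  print(table(x$status))
  invisible(x)
}

#' Completeness of the observed data
#'
#' Fraction of reflections inside the resolution sphere that carry a measured
#' amplitude (statuses observed/free/low_res_replaced).
#'
#' @param data A [reflection_set()].
#' @export
completeness <- function(data) {
  mean(data$status != "missing")
}

# match rows of sf/refl tables by hkl; returns index of `b` rows aligned to `a`
# (NA where absent)
match_hkl <- function(a, b) {
  match(paste(a$h, a$k, a$l), paste(b$h, b$k, b$l))
}
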