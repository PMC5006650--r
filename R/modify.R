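#' HIO feedback parameters
#'
#' @param epsilon Negative-feedback coefficient in (0, 1]; 0.9 is used
#'   throughout the reference calculations.
#' @param clamp Maximum |density| allowed for the solvent-region output
#'   (e/A^3), > 0. Limiting the HIO-modified solvent density markedly improves
#'   convergence; it starts at +/-1.0 and is ramped down to a small final
#'   value as HIO is turned off.
#' @param active If FALSE the solvent update degenerates to clamped
#'   flattening toward zero.
#' @return Object of class `hio_params`.
#' @export
hio_params <- function(epsilon = 0.9, clamp = 1.0, active = TRUE) {
  stopifnot(epsilon > 0, epsilon <= 1, clamp > 0)
  structure(list(epsilon = epsilon, clamp = clamp, active = active),
            class = "hio_params")
}

#' Hybrid input-output density update
#'
#' Inside the protein mask the projected density passes through unchanged (it
#' is histogram-matched separately). Outside the mask (solvent region) the
#' negative-feedback update
#' \deqn{\rho' = \mathrm{clip}(\rho_{in} - \epsilon\,\rho_{out},\; \pm c)}
#' progressively flattens the solvent, where \eqn{\rho_{in}} is the cycle's
#' input density (pre-projection), \eqn{\rho_{out}} the density after the
#' Fourier magnitude projection, and c the clamp.
#'
#' @param rho_prev Input [density_map()] of the current cycle.
#' @param rho_proj [density_map()] after magnitude projection.
#' @param mask [mask_grid()] (TRUE = protein).
#' @param params [hio_params()].
#' @return Updated [density_map()].
#' @export
hio_update <- function(rho_prev, rho_proj, mask, params = hio_params()) {
  if (!identical(dim(rho_prev$values), dim(rho_proj$values)) ||
      !identical(dim(rho_prev$values), dim(mask$values)))
    stop("density and mask grids are not commensurate")
  out <- rho_proj$values
  sol <- !mask$values
  v <- if (params$active)
    rho_prev$values[sol] - params$epsilon * rho_proj$values[sol]
  else rep(0, sum(sol))
  out[sol] <- pmin(pmax(v, -params$clamp), params$clamp)
  density_map(out, rho_proj$cell)
}

#' Solvent clamp schedule
#'
#' The allowed maximum |density| in the solvent region: constant at
#' `initial_clamp` up to `plateau_end`, then geometric interpolation down to
#' `final_clamp` over `window` cycles (HIO slowly turned off), then constant.
#'
#' @param cycle Cycle index (1-based).
#' @param plateau_end Last cycle of the full-clamp plateau.
#' @param window Number of cycles of the turn-off ramp.
#' @param final_clamp Final clamp (e/A^3), > 0.
#' @param initial_clamp Starting clamp (default 1.0 e/A^3).
#' @return Clamp in force at `cycle`.
#' @examples
#' clamp_schedule(100, 200, 200, 0.01)  # 1.0
#' clamp_schedule(300, 200, 200, 0.01)  # 0.1 (geometric midpoint)
#' clamp_schedule(400, 200, 200, 0.01)  # 0.01
#' @export
clamp_schedule <- function(cycle, plateau_end, window, final_clamp,
                           initial_clamp = 1.0) {
  if (final_clamp <= 0) stop("final_clamp must be positive")
  if (cycle <= plateau_end) return(initial_clamp)
  t <- min(1, (cycle - plateau_end) / window)
  initial_clamp * (final_clamp / initial_clamp)^t
}

#' Reference density histogram for the protein region
#'
#' Sorted density values of the template map inside its loose mask, expressed
#' on the scale the iteration works on: HIO flattens the solvent toward zero,
#' so the reference is anchored by subtracting the template map's mean
#' solvent density. With a numeric `offset` the values are additionally
#' shifted so the protein-region mean sits exactly `offset` e/A^3 above the
#' (zero) solvent level, matching protocols for real crystals where the
#' protein-solvent contrast is genuinely small; `offset = NULL` keeps the
#' template's natural contrast.
#'
#' @param template_map [density_map()] of the template model (F(000)-free
#'   scale).
#' @param loose_mask [mask_grid()] delineating the protein region.
#' @param offset Target protein-mean density above the solvent level
#'   (e/A^3, default 0.05), or NULL for the template's natural contrast.
#' @return Object of class `ref_histogram`: list(values = sorted numeric, n).
#' @export
reference_histogram <- function(template_map, loose_mask, offset = 0.05) {
  inside <- template_map$values[loose_mask$values]
  if (length(inside) < 2) stop("loose mask selects fewer than 2 voxels")
  outside_mean <- mean(template_map$values[!loose_mask$values])
  inside <- inside - outside_mean
  if (!is.null(offset)) inside <- inside + (offset - mean(inside))
  structure(list(values = sort(inside), n = length(inside)),
            class = "ref_histogram")
}

#' Histogram matching inside the protein mask
#'
#' Rank-based remapping: the i-th ranked voxel inside the mask is replaced by
#' the reference quantile at the same rank (linear interpolation when counts
#' differ; exact equality when they match). Ranks, and hence the spatial
#' ordering of density, are preserved; ties are broken by voxel
#' (column-major) index. Voxels outside the mask are untouched.
#'
#' @param map A [density_map()].
#' @param mask A [mask_grid()].
#' @param ref A [reference_histogram()].
#' @return A [density_map()].
#' @export
histogram_match <- function(map, mask, ref) {
  if (!inherits(ref, "ref_histogram") || ref$n < 2)
    stop("reference histogram must hold at least 2 values")
  idx <- which(mask$values)
  if (length(idx) == 0) stop("empty protein mask")
  vals <- map$values[idx]
  n <- length(vals)
  ord <- order(vals)  # stable; ties by linear voxel index
  probs <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  mapped <- quantile(ref$values, probs = probs, names = FALSE, type = 7)
  out <- map$values
  out[idx[ord]] <- mapped
  density_map(out, map$cell)
}
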