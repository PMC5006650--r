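# Squared minimum-image Cartesian distance from the origin voxel to every
# voxel offset of the grid (used for kernels and atom placement).
grid_r2 <- function(cell, dims) {
  m <- frac_to_cart(cell)
  ax <- function(n) {
    i <- 0:(n - 1)
    ifelse(i > n / 2, i - n, i) / n
  }
  u1 <- ax(dims[1]); u2 <- ax(dims[2]); u3 <- ax(dims[3])
  U1 <- array(rep(u1, times = dims[2] * dims[3]), dims)
  U2 <- array(rep(rep(u2, each = dims[1]), times = dims[3]), dims)
  U3 <- array(rep(u3, each = dims[1] * dims[2]), dims)
  x <- m[1, 1] * U1 + m[1, 2] * U2 + m[1, 3] * U3
  y <- m[2, 1] * U1 + m[2, 2] * U2 + m[2, 3] * U3
  z <- m[3, 1] * U1 + m[3, 2] * U2 + m[3, 3] * U3
  x^2 + y^2 + z^2
}

# Gaussian kernel array on the grid, truncated; not normalized.
kernel_array <- function(cell, dims, sigma, truncation = 3 * sigma, r2 = NULL) {
  stopifnot(sigma > 0, truncation >= 3 * sigma - 1e-9)
  if (truncation > min(cell$a, cell$b, cell$c) / 2)
    stop("kernel truncation radius exceeds half the shortest cell edge")
  if (is.null(r2)) r2 <- grid_r2(cell, dims)
  w <- exp(-r2 / (2 * sigma^2))
  w[r2 > truncation^2] <- 0
  w
}

# circular convolution of two commensurate real arrays via FFT
fft_convolve <- function(a, b) {
  Re(fft(fft(a, inverse = TRUE) * fft(b, inverse = TRUE))) / prod(dim(a))
}

#' Gaussian weighted-average density
#'
#' Local averaging used to delineate the protein mask: negative input
#' densities are set to zero, then each voxel receives the kernel-weighted
#' average of its periodic neighbourhood,
#' \deqn{\bar\rho_i = \sum_j w(r_{ij}) \max(\rho_j, 0) / \sum_j w(r_{ij})}
#' with \eqn{w(r) = \exp(-r^2 / 2\sigma^2)} truncated at `truncation`
#' (distances minimum-image Cartesian). The normalization preserves constant
#' maps exactly. The radius sigma controls how aggressively the solvent
#' boundary is smoothed and hence the convergence of the solvent region.
#'
#' @param map A [density_map()].
#' @param sigma Kernel radius in Angstrom (> 0).
#' @param truncation Cutoff radius (default 3*sigma); must stay below half the
#'   shortest cell edge.
#' @return A [density_map()] of weighted-average density.
#' @export
weighted_average <- function(map, sigma, truncation = 3 * sigma) {
  dims <- dim(map$values)
  ker <- kernel_array(map$cell, dims, sigma, truncation)
  rp <- pmax(map$values, 0)
  wa <- fft_convolve(rp, ker) / sum(ker)
  density_map(wa, map$cell)
}

#' Density cutoff realizing a protein-volume fraction
#'
#' The threshold equals the (1 - protein_fraction) quantile of the voxel
#' values: the mask `{w >= threshold}` contains `round(fraction * N)` voxels,
#' ties broken by including larger values first, then by lexicographic
#' (column-major) voxel index.
#'
#' @param wmap Weighted-average [density_map()].
#' @param fraction Target protein volume fraction in (0, 1).
#' @return The density threshold (e/A^3).
#' @export
cutoff_for_fraction <- function(wmap, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  v <- as.vector(wmap$values)
  n_in <- max(1L, round(fraction * length(v)))
  ord <- order(v, decreasing = TRUE)  # stable: ties fall back to linear index
  v[ord[n_in]]
}

# top-fraction voxel selection shared by dynamic_mask / loose_model_mask
select_top_fraction <- function(values, fraction) {
  n_in <- max(1L, round(fraction * length(values)))
  ord <- order(as.vector(values), decreasing = TRUE)
  mask <- array(FALSE, dim(values))
  mask[ord[seq_len(n_in)]] <- TRUE
  mask
}

#' Dynamically evolving protein mask
#'
#' Composition weighted_average -> cutoff-for-fraction -> threshold. Grid
#' points with weighted-average density above the cutoff are taken to be
#' inside the protein mask; the cutoff is adjusted so the mask occupies the
#' requested fraction of the cell (within one voxel).
#'
#' @param map A [density_map()] (typically the current modified density).
#' @param fraction Target protein volume fraction.
#' @param sigma Kernel radius (A).
#' @param truncation Kernel cutoff (default 3*sigma).
#' @return A [mask_grid()] with attribute `threshold`.
#' @export
dynamic_mask <- function(map, fraction, sigma, truncation = 3 * sigma) {
  wa <- weighted_average(map, sigma, truncation)
  mask <- select_top_fraction(wa$values, fraction)
  out <- mask_grid(mask, map$cell)
  attr(out, "threshold") <- cutoff_for_fraction(wa, fraction)
  attr(out, "sigma") <- sigma
  out
}

#' Loose protein mask from a template-model density
#'
#' The loose mask deliberately includes some solvent around the molecule
#' (looseness, capped at 8% of the cell volume) so that the evolving mask can
#' cover most of the true structure early on. A small kernel radius (1 A
#' default) keeps the mask tight to the model.
#'
#' @param template_map [density_map()] computed from the placed template model.
#' @param solvent_fraction Crystal solvent content in (0, 1).
#' @param looseness Extra volume fraction beyond (1 - solvent content);
#'   default 0.05, capped at 0.08.
#' @param sigma Kernel radius (A), default 1.
#' @return A [mask_grid()].
#' @export
loose_model_mask <- function(template_map, solvent_fraction, looseness = 0.05,
                             sigma = 1) {
  looseness <- min(looseness, 0.08)
  fraction <- (1 - solvent_fraction) + looseness
  if (fraction >= 1) stop("protein fraction plus looseness must stay below 1")
  dynamic_mask(template_map, fraction, sigma)
}
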