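# Fourier conventions (crystallographic):
#   F(h) = (V/N) * sum_x rho(x) exp(+2 pi i h.x)   [x fractional on the grid]
#   rho(x) = (1/V) * sum_h F(h) exp(-2 pi i h.x)
# R's stats::fft computes the exp(-...) sum forward, so the forward transform
# here uses fft(..., inverse = TRUE) and the inverse uses fft(...).

# linear (column-major) array indices for Miller indices on an n1 x n2 x n3 grid
hkl_linear_index <- function(hkl, dims) {
  i1 <- hkl[, 1] %% dims[1]
  i2 <- hkl[, 2] %% dims[2]
  i3 <- hkl[, 3] %% dims[3]
  1 + i1 + dims[1] * (i2 + dims[2] * i3)
}

# all Miller indices representable on the grid (fftfreq-style), as an N x 3
# matrix in array order
grid_hkl <- function(dims) {
  ax <- function(n) {
    i <- 0:(n - 1)
    ifelse(i > n / 2, i - n, i)
  }
  h <- ax(dims[1]); k <- ax(dims[2]); l <- ax(dims[3])
  cbind(rep(h, times = dims[2] * dims[3]),
        rep(rep(k, each = dims[1]), times = dims[3]),
        rep(l, each = dims[1] * dims[2]))
}

#' Forward Fourier transform: density map to structure factors
#'
#' Returns the unique-hemisphere structure factors of a real periodic map,
#' scaled by the voxel volume so amplitudes are in electrons. Only reflections
#' with d >= d_min are retained; F(000) is excluded.
#'
#' @param map A [density_map()].
#' @param d_min Resolution cutoff (A). Must be at least twice the largest grid
#'   spacing (Nyquist), else an aliasing error is raised.
#' @return An [sf_set()].
#' @export
map_to_sf <- function(map, d_min) {
  dims <- dim(map$values)
  cell <- map$cell
  spacing <- max(c(cell$a, cell$b, cell$c) / dims)
  if (d_min < 2 * spacing - 1e-9)
    stop(sprintf("d_min %.3f A is below the grid Nyquist limit %.3f A (aliasing)",
                 d_min, 2 * spacing))
  v <- cell_volume(cell)
  farr <- fft(map$values, inverse = TRUE) * (v / prod(dims))
  hkl <- grid_hkl(dims)
  side <- hemisphere_side(hkl[, 1], hkl[, 2], hkl[, 3]) &
    abs(hkl[, 1]) < dims[1] / 2 & abs(hkl[, 2]) < dims[2] / 2 &
    abs(hkl[, 3]) < dims[3] / 2  # Nyquist rows cannot carry a Friedel pair
  hkl <- hkl[side, , drop = FALSE]
  d <- resolution_of(hkl, cell)
  keep <- d >= d_min - 1e-9
  hkl <- hkl[keep, , drop = FALSE]
  sf_set(hkl, farr[hkl_linear_index(hkl, dims)][], cell, d = d[keep])
}

#' Inverse Fourier transform: structure factors to density map
#'
#' Expands the hemisphere to full Hermitian coverage (F(-h) = Conj F(h)) and
#' inverts. The imaginary residue of the result must be numerically zero.
#'
#' @param sf An [sf_set()].
#' @param dims Grid divisions `c(n1, n2, n3)`; must accommodate every index.
#' @return A [density_map()].
#' @export
sf_to_map <- function(sf, dims) {
  cell <- attr(sf, "cell")
  hkl <- as.matrix(sf[, c("h", "k", "l")])
  if (any(abs(hkl) >= matrix(dims, nrow(hkl), 3, byrow = TRUE) / 2))
    stop("grid too coarse for the supplied indices")
  arr <- array(0 + 0i, dims)
  arr[hkl_linear_index(hkl, dims)] <- sf$f
  arr[hkl_linear_index(-hkl, dims)] <- Conj(sf$f)
  rho <- fft(arr) / cell_volume(cell)
  if (max(abs(Im(rho))) > 1e-6 * max(abs(Re(rho)), 1e-12))
    stop("non-Hermitian structure-factor set: inverse transform is not real")
  density_map(Re(rho), cell)
}

#' Reflection replacement policy for the magnitude projection
#'
#' Controls which reflections keep their calculated amplitude during
#' projection. Missing reflections are filled in with calculated values and
#' updated each cycle; free reflections are replaced with calculated values
#' the same way (retaining f_obs only for the free R factor); the
#' lowest-resolution measured reflections may also be handed over to the
#' calculated values since very-low-angle measurements are often unreliable.
#'
#' @param fill_missing Keep calculated values for missing reflections
#'   (default TRUE; FALSE zeroes them).
#' @param replace_free Keep calculated values for free reflections (default
#'   TRUE).
#' @return Object of class `projection_policy`.
#' @export
projection_policy <- function(fill_missing = TRUE, replace_free = TRUE) {
  structure(list(fill_missing = fill_missing, replace_free = replace_free),
            class = "projection_policy")
}

#' Fourier magnitude projection
#'
#' For observed reflections the amplitude is set to f_obs while the calculated
#' phase is preserved. Missing, free and low-res-replaced reflections keep
#' both the calculated amplitude and phase.
#'
#' @param f_calc Complex vector of calculated structure factors aligned with
#'   the rows of `data`, or an [sf_set()] covering all of `data`'s hkl.
#' @param data A [reflection_set()].
#' @param policy A [projection_policy()].
#' @return Complex vector (or [sf_set()] if `f_calc` was one) of projected
#'   structure factors.
#' @export
amplitude_projection <- function(f_calc, data, policy = projection_policy()) {
  was_sf <- inherits(f_calc, "sf_set")
  if (was_sf) {
    idx <- match_hkl(data, f_calc)
    if (anyNA(idx)) stop("f_calc does not cover every reflection in data")
    f <- f_calc$f[idx]
  } else {
    f <- as.complex(f_calc)
    if (length(f) != nrow(data)) stop("f_calc length does not match data")
  }
  impose <- data$status == "observed"
  if (!policy$replace_free) impose <- impose | data$status == "free"
  if (any(impose & is.na(data$f_obs)))
    stop("observed reflection with absent f_obs")
  mod <- Mod(f)
  ph <- ifelse(mod > 0, f / mod, 1 + 0i)
  f[impose] <- data$f_obs[impose] * ph[impose]
  if (!policy$fill_missing) f[data$status == "missing"] <- 0 + 0i
  if (was_sf) sf_set(as.matrix(data[, c("h", "k", "l")]), f,
                     attr(data, "cell"), d = data$d)
  else f
}

#' Flag a free (cross-validation) reflection subset
#'
#' Randomly selects about the requested fraction of the observed reflections
#' and marks them `free`. Deterministic given the seed; the flags persist for
#' the whole run.
#'
#' @param data A [reflection_set()].
#' @param fraction Fraction of observed reflections to hold out (0, 0.5).
#' @param seed Integer RNG seed.
#' @return The reflection set with updated statuses.
#' @export
assign_free_set <- function(data, fraction = 0.02, seed = 1) {
  stopifnot(fraction > 0, fraction < 0.5)
  eligible <- which(data$status == "observed")
  n <- round(fraction * length(eligible))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  pick <- sample(eligible, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  data$status[pick] <- "free"
  data
}

#' Flag the lowest-resolution reflections for replacement
#'
#' Marks the `n` largest-d observed reflections `low_res_replaced`; their
#' amplitudes are handed over to the calculated values during projection.
#' Ties are broken by lexicographic hkl.
#'
#' @param data A [reflection_set()].
#' @param n Number of reflections to flag (or `NULL` to flag all observed
#'   reflections with d > `d_cut`).
#' @param d_cut Resolution threshold used when `n` is NULL (default 25 A).
#' @return The reflection set with updated statuses.
#' @export
select_low_res_replacement <- function(data, n = NULL, d_cut = 25) {
  obs <- which(data$status == "observed")
  if (is.null(n)) {
    pick <- obs[data$d[obs] > d_cut]
  } else {
    stopifnot(n <= length(obs))
    if (n == 0) return(data)
    ord <- obs[order(-data$d[obs], data$h[obs], data$k[obs], data$l[obs])]
    pick <- ord[seq_len(n)]
  }
  data$status[pick] <- "low_res_replaced"
  data
}
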