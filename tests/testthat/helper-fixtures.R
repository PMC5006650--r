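# shared small fixtures, built in code

# band-limited random structure-factor set on a small grid: everything below
# the Nyquist rows and above d_min, so map<->SF round trips are exact
random_sf_fixture <- function(cell, dims, d_min, seed = 1) {
  set.seed(seed)
  hkl <- grid_hkl(dims)
  keep <- hemisphere_side(hkl[, 1], hkl[, 2], hkl[, 3]) &
    abs(hkl[, 1]) < dims[1] / 2 & abs(hkl[, 2]) < dims[2] / 2 &
    abs(hkl[, 3]) < dims[3] / 2
  hkl <- hkl[keep, , drop = FALSE]
  hkl <- hkl[resolution_of(hkl, cell) >= d_min, , drop = FALSE]
  f <- complex(real = rnorm(nrow(hkl)), imaginary = rnorm(nrow(hkl)))
  sf_set(hkl, f, cell)
}

# direct triple-sum DFT oracle: F(h) = (V/N) sum rho exp(+2 pi i h.x)
dft_oracle <- function(values, cell, hkl) {
  dims <- dim(values)
  v <- cell_volume(cell)
  vapply(seq_len(nrow(hkl)), function(i) {
    s <- 0 + 0i
    for (a in 0:(dims[1] - 1)) for (b in 0:(dims[2] - 1)) for (cc in 0:(dims[3] - 1))
      s <- s + values[a + 1, b + 1, cc + 1] *
        exp(2i * pi * (hkl[i, 1] * a / dims[1] + hkl[i, 2] * b / dims[2] +
                         hkl[i, 3] * cc / dims[3]))
    s * v / prod(dims)
  }, complex(1))
}

# direct double-loop periodic weighted-average oracle (Gaussian kernel)
weighted_average_oracle <- function(values, cell, sigma, truncation = 3 * sigma) {
  dims <- dim(values)
  rp <- pmax(values, 0)
  r2 <- grid_r2(cell, dims)
  w <- exp(-r2 / (2 * sigma^2))
  w[r2 > truncation^2] <- 0
  out <- array(0, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    s <- 0; sw <- 0
    for (a in 1:dims[1]) for (b in 1:dims[2]) for (cc in 1:dims[3]) {
      ww <- w[((i - a) %% dims[1]) + 1, ((j - b) %% dims[2]) + 1,
              ((k - cc) %% dims[3]) + 1]
      s <- s + ww * rp[a, b, cc]
      sw <- sw + ww
    }
    out[i, j, k] <- s / sw
  }
  out
}

# tiny toy crystal shared across engine tests (cached per session)
toy_cache <- new.env(parent = emptyenv())
get_toy <- function(seed = 1, solvent_fraction = 0.75) {
  key <- sprintf("s%d_f%g", seed, solvent_fraction)
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- make_toy_crystal(seed = seed,
                                         solvent_fraction = solvent_fraction)
  toy_cache[[key]]
}
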