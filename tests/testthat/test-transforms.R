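test_that("map_to_sf agrees with a brute-force DFT on random grids", {
  for (seed in 1:3) {
    cell <- unit_cell(8, 9, 10, 85, 92, 101)
    dims <- c(4, 4, 4)
    set.seed(seed)
    m <- density_map(array(rnorm(prod(dims)), dims), cell)
    d_min <- 2 * max(c(cell$a, cell$b, cell$c) / dims)
    sf <- map_to_sf(m, d_min)
    bf <- dft_oracle(m$values, cell, as.matrix(sf[, c("h", "k", "l")]))
    expect_lt(max(Mod(sf$f - bf)) / max(Mod(bf)), 1e-10)
  }
})

test_that("map<->SF round trip is exact for band-limited maps", {
  cell <- unit_cell(8, 9, 10, 85, 92, 101)
  dims <- c(4, 4, 4)
  d_min <- 2 * max(c(cell$a, cell$b, cell$c) / dims)
  sf0 <- random_sf_fixture(cell, dims, d_min, seed = 2)
  m <- sf_to_map(sf0, dims)
  sf1 <- map_to_sf(m, d_min)
  idx <- match_hkl(sf0, sf1)
  expect_false(anyNA(idx))
  expect_lt(max(Mod(sf0$f - sf1$f[idx])), 1e-10)
  m2 <- sf_to_map(sf1, dims)
  expect_lt(max(abs(m$values - m2$values)), 1e-10)
})

test_that("degenerate spectra behave: constant and delta maps", {
  cell <- unit_cell(12, 12, 12)
  dims <- c(6, 6, 6)
  const <- density_map(array(2.5, dims), cell)
  sfc <- map_to_sf(const, 4)
  expect_lt(max(Mod(sfc$f)), 1e-10)  # DC-only spectrum, F000 excluded

  spike <- array(0, dims); spike[1, 1, 1] <- 1
  sf <- map_to_sf(density_map(spike, cell), 4)
  vv <- cell_volume(cell) / prod(dims)
  expect_true(all(abs(Mod(sf$f) - vv) < 1e-12))  # flat spectrum of a delta

  expect_error(map_to_sf(const, 1), "Nyquist")
})

test_that("single-reflection inverse transform is the expected cosine wave", {
  cell <- unit_cell(10, 10, 10)
  dims <- c(10, 10, 10)
  a <- 7
  sf <- sf_set(rbind(c(1, 0, 0)), complex(real = a), cell)
  m <- sf_to_map(sf, dims)
  v <- cell_volume(cell)
  x <- (0:9) / 10
  expect_equal(m$values[, 1, 1], 2 * a / v * cos(2 * pi * x), tolerance = 1e-12)
})

test_that("Parseval holds between map and structure factors", {
  cell <- unit_cell(8, 9, 10, 85, 92, 101)
  dims <- c(4, 4, 4)
  d_min <- 2 * max(c(cell$a, cell$b, cell$c) / dims)
  sf <- random_sf_fixture(cell, dims, d_min, seed = 3)
  m <- sf_to_map(sf, dims)
  v <- cell_volume(cell)
  # Friedel mates double the hemisphere sum; F000 = 0 for this fixture
  expect_equal(mean(m$values^2), 2 * sum(Mod(sf$f)^2) / v^2,
               tolerance = 1e-8)
})

test_that("amplitude projection imposes f_obs and preserves phases", {
  cell <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
  data <- reflection_set(hkl, c(10, 3, NA, 5), cell, d_min = 5,
                         status = c("observed", "observed", "missing", "free"))
  f_calc <- complex(modulus = c(2, 3, 3, 8),
                    argument = c(30, 120, 45, -60) * pi / 180)
  out <- amplitude_projection(f_calc, data)
  expect_equal(Mod(out[1]), 10)                      # amplitude from data
  expect_equal(Arg(out[1]), 30 * pi / 180)           # phase preserved
  expect_equal(out[2], f_calc[2] / Mod(f_calc[2]) * 3)
  expect_equal(out[3], f_calc[3])                    # missing: calculated kept
  expect_equal(out[4], f_calc[4])                    # free: calculated kept
  # idempotence per reflection
  expect_equal(amplitude_projection(out, data), out)
  # satisfied constraints are fixed points
  sat <- complex(modulus = c(10, 3, 1, 1), argument = c(1, 2, 3, 4))
  expect_equal(amplitude_projection(sat, data), sat)
  # exact residual on observed reflections after projection
  expect_equal(sum((Mod(out[1:2]) - data$f_obs[1:2])^2), 0)
})

test_that("zero calculated amplitude projects onto phase zero", {
  cell <- unit_cell(10, 10, 10)
  data <- reflection_set(rbind(c(1, 0, 0)), 4, cell, d_min = 5)
  out <- amplitude_projection(0 + 0i, data)
  expect_equal(out, 4 + 0i)
})

test_that("free-set assignment is seeded, sized and persistent", {
  toy <- get_toy()
  data <- toy$data
  n_obs <- sum(data$status == "observed")
  a <- assign_free_set(data, 0.02, seed = 7)
  expect_equal(sum(a$status == "free"), round(0.02 * n_obs))
  b <- assign_free_set(data, 0.02, seed = 7)
  expect_identical(a$status, b$status)
  # different seeds give different sets (checked over 10 pairs)
  diffs <- vapply(1:10, function(s) {
    x <- assign_free_set(data, 0.02, seed = s)
    y <- assign_free_set(data, 0.02, seed = s + 100)
    !identical(which(x$status == "free"), which(y$status == "free"))
  }, logical(1))
  expect_true(all(diffs))
})

test_that("low-resolution replacement flags the largest-d reflections", {
  toy <- get_toy()
  data <- toy$data
  expect_identical(select_low_res_replacement(data, 0), data)
  one <- select_low_res_replacement(data, 1)
  i <- which(one$status == "low_res_replaced")
  expect_equal(length(i), 1)
  expect_equal(data$d[i], max(data$d))
  ten <- select_low_res_replacement(data, 10)
  flagged <- which(ten$status == "low_res_replaced")
  # brute-force oracle: sort by d descending, ties by lexicographic hkl
  ord <- order(-data$d, data$h, data$k, data$l)
  expect_setequal(flagged, ord[1:10])
})
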