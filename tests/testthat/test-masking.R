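test_that("weighted average matches the direct periodic convolution oracle", {
  cell <- unit_cell(16, 16, 16)
  dims <- c(8, 8, 8)
  set.seed(3)
  m <- density_map(array(rnorm(prod(dims)), dims), cell)
  wa <- weighted_average(m, sigma = 2)
  bf <- weighted_average_oracle(m$values, cell, sigma = 2)
  expect_lt(max(abs(wa$values - bf)), 1e-10)

  # single spike: direct check of kernel shape and normalization
  spike <- array(0, dims); spike[3, 5, 2] <- 1
  was <- weighted_average(density_map(spike, cell), 2)
  bfs <- weighted_average_oracle(spike, cell, 2)
  expect_lt(max(abs(was$values - bfs)), 1e-10)
})

test_that("weighted average preserves constants, zeroes negatives, stays bounded", {
  cell <- unit_cell(16, 16, 16)
  dims <- c(8, 8, 8)
  const <- density_map(array(3.3, dims), cell)
  expect_equal(weighted_average(const, 2)$values, array(3.3, dims),
               tolerance = 1e-12)
  neg <- density_map(array(-1, dims), cell)
  expect_equal(max(abs(weighted_average(neg, 2)$values)), 0)
  set.seed(4)
  r <- density_map(array(rnorm(prod(dims)), dims), cell)
  wa <- weighted_average(r, 1.5)
  rp <- pmax(r$values, 0)
  expect_gte(min(wa$values), min(rp) - 1e-12)
  expect_lte(max(wa$values), max(rp) + 1e-12)
  expect_error(weighted_average(r, 4), "truncation")  # 3*sigma > half edge
})

test_that("small-sigma weighted average approaches the identity on positives", {
  cell <- unit_cell(16, 16, 16)
  dims <- c(8, 8, 8)
  set.seed(5)
  vals <- array(abs(rnorm(prod(dims))), dims)
  wa <- weighted_average(density_map(vals, cell), sigma = 0.2)
  expect_lt(max(abs(wa$values - vals)), 1e-6)
})

test_that("cutoff_for_fraction equals the sorted-selection oracle", {
  cell <- unit_cell(10, 10, 10)
  v4 <- density_map(array(c(4, 2, 1, 3, 8, 7, 6, 5), c(2, 2, 2)), cell)
  expect_equal(cutoff_for_fraction(v4, 1 / 8), 8)    # only the largest
  expect_equal(cutoff_for_fraction(v4, 0.999), 1)    # everything inside

  set.seed(6)
  dims <- c(10, 10, 10)
  w <- density_map(array(runif(1000), dims), cell)
  thr <- cutoff_for_fraction(w, 0.35)
  ord <- sort(as.vector(w$values), decreasing = TRUE)
  expect_equal(thr, ord[round(0.35 * 1000)])
  mask <- dynamic_mask(w, 0.35, sigma = 0.2)
  expect_equal(sum(mask$values), round(0.35 * 1000))
})

test_that("dynamic_mask recovers a ball support and smooths with sigma", {
  cell <- unit_cell(20, 20, 20)
  dims <- c(20, 20, 20)
  r2 <- grid_r2(cell, dims)
  ball <- array(as.numeric(r2 <= 6^2), dims)   # centred at voxel (1,1,1)
  frac <- mean(ball > 0)
  m <- density_map(ball, cell)
  mask <- dynamic_mask(m, frac, sigma = 0.8)
  jacc <- sum(mask$values & ball > 0) / sum(mask$values | ball > 0)
  expect_gte(jacc, 0.95)
  # fraction error bounded by one voxel
  expect_lte(abs(protein_fraction(mask) - frac), 1 / prod(dims) + 1e-12)

  # on a noisy ball, a wider kernel smooths the mask boundary
  boundary_faces <- function(msk) {
    s <- 0
    for (ax in 1:3) {
      shifted <- apply(msk, setdiff(1:3, ax), function(line)
        line != c(line[-1], line[1]))
      s <- s + sum(shifted)
    }
    s
  }
  set.seed(7)
  noisy <- density_map(ball + array(rnorm(prod(dims), sd = 0.5), dims), cell)
  b1 <- boundary_faces(dynamic_mask(noisy, frac, sigma = 0.3)$values)
  b2 <- boundary_faces(dynamic_mask(noisy, frac, sigma = 2)$values)
  expect_lt(b2, b1)
})

test_that("uniform maps give the defined tie-broken mask", {
  cell <- unit_cell(10, 10, 10)
  u <- density_map(array(1, c(4, 4, 4)), cell)
  mask <- dynamic_mask(u, 0.25, sigma = 0.5)
  expect_equal(which(mask$values), 1:16)  # first voxels in linear order
})

test_that("loose model mask hits the requested volume and covers the model", {
  toy <- get_toy()
  dims <- grid_for_resolution(toy$model$cell, 3, 3)
  tmap <- model_to_density(toy$model, dims)
  lm <- loose_model_mask(tmap, solvent_fraction = 0.77, looseness = 0.05)
  expect_equal(protein_fraction(lm), 0.28, tolerance = 1e-3)
  lm0 <- loose_model_mask(tmap, solvent_fraction = 0.77, looseness = 0)
  expect_equal(protein_fraction(lm0), 0.23, tolerance = 1e-3)
  # looseness is capped at 8% of the cell
  lm9 <- loose_model_mask(tmap, solvent_fraction = 0.77, looseness = 0.2)
  expect_equal(protein_fraction(lm9), 0.31, tolerance = 1e-3)
  expect_error(loose_model_mask(tmap, solvent_fraction = 0.01), "below 1")

  # every atom's nearest voxel lies inside a loose mask of its own model
  lm2 <- loose_model_mask(tmap, solvent_fraction = toy$spec$solvent_fraction,
                          looseness = 0.05)
  minv <- solve(frac_to_cart(toy$model$cell))
  frac <- t(minv %*% t(as.matrix(toy$model$atoms[, c("x", "y", "z")]))) %% 1
  vox <- cbind(round(frac[, 1] * dims[1]) %% dims[1] + 1,
               round(frac[, 2] * dims[2]) %% dims[2] + 1,
               round(frac[, 3] * dims[3]) %% dims[3] + 1)
  expect_gte(mean(lm2$values[vox]), 0.99)
})
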