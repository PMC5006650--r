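test_that("mean phase error: closed forms and the uniform-phase expectation", {
  cell <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  f <- complex(modulus = c(3, 2, 1), argument = c(0.4, -1.2, 2.9))
  a <- sf_set(hkl, f, cell)
  expect_equal(mean_phase_error(a, a), 0)
  b <- sf_set(hkl, -f, cell)
  expect_equal(mean_phase_error(a, b), 180)
  # E|wrapped difference of independent uniforms| = 90 degrees
  set.seed(12)
  n <- 1e5
  d1 <- runif(n, -pi, pi); d2 <- runif(n, -pi, pi)
  dphi <- abs(((d1 - d2) * 180 / pi + 180) %% 360 - 180)
  expect_equal(mean(dphi), 90, tolerance = 0.5 / 90)
  expect_error(mean_phase_error(a, sf_set(rbind(c(0, 0, 5)),
                                          complex(real = 1), cell)),
               "no common")
})

test_that("mean phase error weights by observed amplitude", {
  cell <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0))
  ref <- sf_set(hkl, complex(modulus = 1, argument = c(0, 0)), cell)
  cur <- sf_set(hkl, complex(modulus = 1, argument = c(0, pi / 2)), cell)
  data <- reflection_set(hkl, c(9, 1), cell, d_min = 5)
  expect_equal(mean_phase_error(ref, cur, data), 9)      # (9*0 + 1*90)/10
  expect_equal(mean_phase_error(ref, cur), 45)           # unweighted
})

test_that("free R: scale invariance, two-reflection closed form, random band", {
  cell <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0))
  data <- reflection_set(hkl, c(10, 20), cell, d_min = 5,
                         status = c("free", "free"))
  # proportional amplitudes are absorbed by the scale
  expect_equal(r_free(complex(modulus = c(5, 10), argument = 1), data), 0)
  # hand computation: k = (10*1 + 20*4)/(1+16) = 90/17
  k <- 90 / 17
  expect_equal(r_free(complex(modulus = c(1, 4), argument = 0), data),
               (abs(10 - k) + abs(20 - 4 * k)) / 30)
  expect_error(r_free(complex(modulus = c(1, 4), argument = 0),
                      reflection_set(hkl, c(10, 20), cell, d_min = 5)),
               "empty free set")

  # amplitudes of an unrelated structure: R_free in the uncorrelated band
  toy <- get_toy(seed = 1)
  data2 <- assign_free_set(toy$data, 0.05, seed = 2)
  rs <- vapply(1:10, function(s) {
    other <- make_toy_crystal(seed = 500 + s)
    idx <- match_hkl(data2, other$data)
    r_free(complex(modulus = other$data$f_obs[idx], argument = 0), data2)
  }, numeric(1))
  expect_true(all(rs > 0.4 & rs < 0.7))
})

test_that("convergence detection distinguishes steps from flat and jittery traces", {
  flat <- rep(0.55, 400)
  expect_true(is.na(detect_convergence(flat)))
  step <- c(rep(0.55, 299), rep(0.35, 101))
  t <- detect_convergence(step)
  expect_false(is.na(t))
  expect_lte(abs(t - 300), 100)
  set.seed(13)
  jitter <- 0.55 + 0.01 * sin(1:400) * rep(c(1, -1), 200)
  expect_true(is.na(detect_convergence(jitter)))
  # a settling transient (high start, settle at mid level) is not a drop
  settle <- c(seq(0.30, 0.58, length.out = 60), seq(0.58, 0.40, length.out = 140),
              rep(0.40, 200))
  expect_true(is.na(detect_convergence(settle)))
})

test_that("map-model correlation: exact limits and the SNR=1 prediction", {
  toy <- get_toy()
  dims <- grid_for_resolution(toy$model$cell, 3, 3)
  md <- model_to_density(toy$model, dims)
  expect_equal(map_model_cc(md, toy$model), 1.0)
  neg <- density_map(-md$values, md$cell)
  expect_equal(map_model_cc(neg, toy$model), -1.0)
  expect_error(map_model_cc(density_map(array(1, dims), md$cell), toy$model),
               "zero-variance")
  # CC of signal + noise at SNR 1 -> 1/sqrt(2)
  ccs <- vapply(1:10, function(s) {
    set.seed(s)
    noisy <- density_map(md$values + rnorm(length(md$values), sd = sd(md$values)),
                         md$cell)
    map_model_cc(noisy, toy$model)
  }, numeric(1))
  expect_equal(mean(ccs), 1 / sqrt(2), tolerance = 0.03 / 0.7)
})

test_that("the run loop is deterministic and records its schedules", {
  toy <- get_toy()
  cfg <- phasing_config(total_cycles = 8, solvent_fraction = 0.75, seed = 42,
                        histogram_matching = FALSE)
  r1 <- run_phasing(toy$data, cfg, start_phases = toy$true_phases)
  r2 <- run_phasing(toy$data, cfg, start_phases = toy$true_phases)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$sf$f, r2$sf$f)
  expect_true(all(r1$trace$epsilon == 0.9))
  expect_true(all(is.finite(r1$trace$r_free)))
  # sigma schedule is linear between its endpoints
  expect_equal(r1$trace$sigma, seq(3, 2, length.out = 8))
  # random starts are seeded too
  cfgr <- phasing_config(total_cycles = 5, solvent_fraction = 0.75, seed = 7,
                         start_mode = "random", histogram_matching = FALSE)
  a <- run_phasing(toy$data, cfgr)
  b <- run_phasing(toy$data, cfgr)
  expect_identical(a$trace, b$trace)
  cfgr2 <- phasing_config(total_cycles = 5, solvent_fraction = 0.75, seed = 8,
                          start_mode = "random", histogram_matching = FALSE)
  expect_false(identical(a$sf$f, run_phasing(toy$data, cfgr2)$sf$f))
})

test_that("with a near-whole-cell mask the loop reduces to magnitude projection", {
  toy <- get_toy()
  cfg <- phasing_config(total_cycles = 10, solvent_fraction = 0.02,
                        looseness = 0, sigma_start = 2, sigma_end = 2,
                        epsilon = 1e-9, clamp_plateau = 10,
                        initial_clamp = 100, final_clamp = 100, seed = 1,
                        histogram_matching = FALSE, d_min_extend = 1)
  res <- run_phasing(toy$data, cfg, start_phases = toy$true_phases,
                     reference_phases = toy$true_phases)
  # true phases + true amplitudes are a fixed point of pure projection
  expect_lt(max(res$trace$phase_error), 1)
})

test_that("phase error traces stay within their physical ranges", {
  toy <- get_toy()
  cfg <- phasing_config(total_cycles = 15, solvent_fraction = 0.75, seed = 3,
                        start_mode = "random", histogram_matching = FALSE)
  res <- run_phasing(toy$data, cfg, reference_phases = toy$true_phases)
  expect_true(all(res$trace$phase_error >= 0 & res$trace$phase_error <= 180))
  expect_true(all(res$trace$r_free >= 0))
  expect_true(all(diff(res$trace$clamp) <= 1e-12))  # clamp never increases
})

test_that("origin alignment recovers a deliberate translation", {
  toy <- get_toy()
  dims <- grid_for_resolution(toy$model$cell, 3, 3)
  hkl <- as.matrix(toy$true_phases[, c("h", "k", "l")])
  t_frac <- c(8, 3, 0) / dims  # a grid translation
  shifted <- sf_set(hkl, toy$true_phases$f *
                      exp(2i * pi * as.vector(hkl %*% t_frac)),
                    toy$model$cell)
  raw <- mean_phase_error(toy$true_phases, shifted, toy$data)
  aligned <- aligned_phase_error(toy$true_phases, shifted, toy$data, dims)
  expect_gt(raw, 30)
  expect_lt(aligned, 1e-6)
})
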