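# fraction of grid voxels lying within `radius` A of any atom (periodic)
envelope_fraction <- function(atoms_xyz, cell, dims, radius) {
  m <- frac_to_cart(cell); minv <- solve(m)
  reach <- sqrt(rowSums(minv^2))
  inside <- array(FALSE, dims)
  frac <- t(minv %*% t(atoms_xyz)) %% 1
  nf <- pmin(ceiling(reach * radius * dims) + 1L, floor((dims - 1) / 2))
  for (i in seq_len(nrow(atoms_xyz))) {
    ctr <- round(frac[i, ] * dims)
    i1 <- (ctr[1] - nf[1]):(ctr[1] + nf[1])
    i2 <- (ctr[2] - nf[2]):(ctr[2] + nf[2])
    i3 <- (ctr[3] - nf[3]):(ctr[3] + nf[3])
    u1 <- i1 / dims[1] - frac[i, 1]
    u2 <- i2 / dims[2] - frac[i, 2]
    u3 <- i3 / dims[3] - frac[i, 3]
    n1 <- length(u1); n2 <- length(u2); n3 <- length(u3)
    U1 <- array(rep(u1, times = n2 * n3), c(n1, n2, n3))
    U2 <- array(rep(rep(u2, each = n1), times = n3), c(n1, n2, n3))
    U3 <- array(rep(u3, each = n1 * n2), c(n1, n2, n3))
    x <- m[1, 1] * U1 + m[1, 2] * U2 + m[1, 3] * U3
    y <- m[2, 1] * U1 + m[2, 2] * U2 + m[2, 3] * U3
    z <- m[3, 1] * U1 + m[3, 2] * U2 + m[3, 3] * U3
    hit <- (x^2 + y^2 + z^2) <= radius^2
    inside[(i1 %% dims[1]) + 1, (i2 %% dims[2]) + 1, (i3 %% dims[3]) + 1] <-
      inside[(i1 %% dims[1]) + 1, (i2 %% dims[2]) + 1, (i3 %% dims[3]) + 1] | hit
  }
  mean(inside)
}

#' Generate a synthetic toy crystal
#'
#' Builds a pseudo-protein as a chain of residues: residue centres follow a
#' seeded compact random walk with a 3.8 A step (a C-alpha-trace spacing)
#' confined to a ball at the cell centre, and each residue carries a blob of
#' carbon-like atoms scattered around its centre (1.6 A spread), giving the
#' density the chunky, tube-like character of real protein at moderate
#' resolution. The confining radius is tuned (coarse scan plus bisection) so
#' the dilated protein envelope occupies 1 - `solvent_fraction` of the cell
#' within +/-0.03. Amplitudes are computed from the resulting density; the
#' true phases are returned separately for scoring and never enter the
#' "observed" set.
#'
#' @param cell A [unit_cell()] (default cubic 30 A).
#' @param n_atoms Approximate number of pseudo-atoms. The default (NULL)
#'   scales with the target protein volume at one atom per 6.75 A^3, the
#'   packing at which the chain just fills its envelope.
#' @param solvent_fraction Solvent content in \[0.4, 0.9\] (default 0.75).
#' @param d_min Resolution cutoff (A, default 3).
#' @param b_mean Atomic B factor (A^2, default 50; typical of crystals
#'   diffracting to ~3 A).
#' @param seed Integer seed.
#' @param noise_frac Optional multiplicative Gaussian amplitude noise
#'   fraction (default 0 = noise-free).
#' @param atoms_per_residue Blob size (default 8, about one side chain's
#'   worth of non-hydrogen atoms plus backbone).
#' @param envelope_radius Dilation radius defining the protein envelope (A).
#' @param oversample Grid oversampling factor.
#' @return List with `model` ([atomic_model()]; atoms carry a `resid`
#'   column), `data` ([reflection_set()] of observed amplitudes),
#'   `true_phases` ([sf_set()]), `envelope_fraction` (realized protein
#'   volume fraction) and `spec` (the generating parameters).
#' @export
make_toy_crystal <- function(cell = unit_cell(30, 30, 30), n_atoms = NULL,
                             solvent_fraction = 0.75, d_min = 3,
                             b_mean = 50, seed = 1, noise_frac = 0,
                             atoms_per_residue = 8, envelope_radius = 2.5,
                             oversample = 3) {
  stopifnot(solvent_fraction >= 0.4, solvent_fraction <= 0.9)
  target <- 1 - solvent_fraction
  if (is.null(n_atoms))
    n_atoms <- round(target * cell_volume(cell) / 6.75)
  stopifnot(n_atoms >= 10)
  step <- 3.8
  dims <- grid_for_resolution(cell, d_min, oversample)
  centre <- as.numeric(frac_to_cart(cell) %*% c(0.5, 0.5, 0.5))
  # the confining ball may extend past the half-edge: molecules in real
  # crystals contact their periodic neighbours, and the envelope is measured
  # periodically, so overlap with images is legitimate
  r_hi <- 0.7 * min(cell$a, cell$b, cell$c)
  r_analytic <- (target * cell_volume(cell) * 3 / (4 * pi))^(1 / 3) - envelope_radius
  if (r_analytic >= r_hi)
    stop("infeasible packing: required ball exceeds the unit cell")
  set.seed(seed)
  n_res <- max(2L, round(n_atoms / atoms_per_residue))
  result <- NULL
  for (attempt in 1:4) {
    # walk directions and blob offsets fixed per attempt so the chain shape
    # is stable under rescaling of the confining ball
    dirs <- matrix(rnorm(3 * n_res), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    offs <- matrix(rnorm(3 * n_res * atoms_per_residue, sd = 1.6), ncol = 3)
    walk_in_ball <- function(r) {
      pts <- matrix(0, n_res, 3)
      x <- c(0, 0, 0)
      for (i in seq_len(n_res)) {
        cand <- x + step * dirs[i, ]
        if (sum(cand^2) > r^2) cand <- x - step * dirs[i, ]
        if (sum(cand^2) > r^2) cand <- x  # corner case: stay put
        x <- cand
        pts[i, ] <- x
      }
      pts
    }
    atoms_at <- function(r) {
      ctr <- walk_in_ball(r)
      sweep(ctr[rep(seq_len(n_res), each = atoms_per_residue), ] + offs,
            2, centre, "+")
    }
    frac_at <- function(r) envelope_fraction(atoms_at(r), cell, dims, envelope_radius)
    # coverage rises with the ball radius while the chain can still fill it,
    # then falls as it spreads thin: scan coarsely, then bisect on the
    # rising branch around the target
    grid_r <- seq(max(2, r_analytic / 2), r_hi, length.out = 10)
    grid_f <- vapply(grid_r, frac_at, numeric(1))
    if (max(grid_f) < target - 0.02) {
      n_res <- round(n_res * 1.3)  # chain too sparse: densify and retry
      next
    }
    i_up <- which(grid_f >= target)[1]
    if (is.na(i_up)) i_up <- which.max(grid_f)
    lo <- if (i_up > 1) grid_r[i_up - 1] else max(0.5, grid_r[1] / 2)
    hi <- grid_r[i_up]
    r <- (lo + hi) / 2
    for (it in 1:20) {
      fr <- frac_at(r)
      if (abs(fr - target) <= 0.02) break
      if (fr < target) lo <- r else hi <- r
      r <- (lo + hi) / 2
    }
    result <- list(r = r)
    break
  }
  if (is.null(result))
    stop("infeasible packing: cannot reach the requested protein fraction")
  xyz <- atoms_at(result$r)
  model <- atomic_model(cell, data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], elem = "C", occ = 1,
    b = b_mean, resid = rep(seq_len(n_res), each = atoms_per_residue)))
  rho <- model_to_density(model, dims)
  sf_true <- map_to_sf(rho, d_min)
  amp <- Mod(sf_true$f)
  if (noise_frac > 0)
    amp <- pmax(amp * (1 + noise_frac * rnorm(length(amp))), 0)
  data <- reflection_set(as.matrix(sf_true[, c("h", "k", "l")]), amp,
                         cell, d_min)
  list(model = model, data = data, true_phases = sf_true,
       envelope_fraction = envelope_fraction(xyz, cell, dims, envelope_radius),
       spec = list(n_atoms = nrow(model$atoms), n_res = n_res,
                   solvent_fraction = solvent_fraction,
                   d_min = d_min, b_mean = b_mean, seed = seed,
                   ball_radius = result$r))
}

#' Degrade a template model
#'
#' Emulates a distant-homolog search model. When the model carries a `resid`
#' column (toy crystals do), a fraction of whole residues is deleted
#' (unalignable segments stripped from the search model) and the survivors
#' are displaced by a smooth along-chain field plus per-atom jitter -
#' mimicking a homolog whose segments shift coherently while local
#' conformations are wrong. Without residue information the same operations
#' act per atom. Displacements are rescaled so the realized coordinate RMSD
#' matches the request exactly.
#'
#' @param model An [atomic_model()].
#' @param coord_noise_rmsd Total coordinate displacement RMSD (A, >= 0).
#' @param trim_fraction Fraction of residues side-chain-trimmed (or atoms
#'   deleted, for residue-less models) in \[0, 1).
#' @param seed Integer seed.
#' @param atom_jitter RMSD (A) of the per-atom component of the displacement
#'   (default 1.5, capped at the total RMSD); the remainder goes into the
#'   smooth segment-shift field.
#' @return The degraded [atomic_model()].
#' @export
degrade_template <- function(model, coord_noise_rmsd = 0, trim_fraction = 0,
                             seed = 1, atom_jitter = 1.5) {
  stopifnot(coord_noise_rmsd >= 0, trim_fraction >= 0, trim_fraction < 1)
  at <- model$atoms
  set.seed(seed)
  if (!is.null(at$resid)) {
    # whole residues are deleted, emulating the unalignable loops and
    # termini stripped from search models before molecular replacement
    res <- unique(at$resid)
    keep_res <- sort(sample(length(res),
                            length(res) - round(trim_fraction * length(res))))
    at <- at[at$resid %in% res[keep_res], , drop = FALSE]
    if (nrow(at) < 5) stop("trim_fraction leaves fewer than 5 atoms")
    if (coord_noise_rmsd > 0) {
      # homolog-style coordinate error, two components: a smooth
      # displacement field along the chain (segments shift coherently, the
      # envelope deforms without scattering), plus per-atom jitter
      # emulating wrong local conformations, which scrambles
      # high-resolution phases while leaving the envelope intact
      res2 <- unique(at$resid)
      nr <- length(res2)
      jitter <- min(atom_jitter, coord_noise_rmsd)
      smooth_rmsd <- sqrt(max(coord_noise_rmsd^2 - jitter^2, 0))
      d <- matrix(rnorm(3 * nr), ncol = 3)
      w <- 7  # smoothing window in residues
      sm <- apply(d, 2, function(col)
        stats::filter(c(col, col[seq_len(min(w, nr))]), rep(1 / w, w),
                      sides = 2)[seq_len(nr)])
      sm[is.na(sm)] <- d[is.na(sm)]
      if (smooth_rmsd > 0)
        sm <- sm * smooth_rmsd / sqrt(mean(rowSums(sm^2)))
      else sm[] <- 0
      rownames(sm) <- as.character(res2)
      aj <- matrix(rnorm(3 * nrow(at)), ncol = 3)
      if (jitter > 0) aj <- aj * jitter / sqrt(mean(rowSums(aj^2)))
      else aj[] <- 0
      at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
        sm[as.character(at$resid), ] + aj
    }
  } else {
    n <- nrow(at)
    n_keep <- n - round(trim_fraction * n)
    if (n_keep < 5) stop("trim_fraction leaves fewer than 5 atoms")
    at <- at[sort(sample(n, n_keep)), , drop = FALSE]
    if (coord_noise_rmsd > 0) {
      d <- matrix(rnorm(3 * nrow(at)), ncol = 3)
      d <- d * coord_noise_rmsd / sqrt(mean(rowSums(d^2)))
      at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] + d
    }
  }
  atomic_model(model$cell, at)
}

#' Starting phase error of a degraded template
#'
#' Amplitude-weighted mean phase error between the true phases and the
#' structure factors of the degraded template, computed exactly as the
#' engine's template start would be. Toy crystals have empty (vacuum)
#' solvent, so no bulk-solvent term is added.
#'
#' @param true_phases [sf_set()] of ground-truth phases.
#' @param degraded Degraded template [atomic_model()].
#' @param data [reflection_set()] supplying the f_obs weights.
#' @param solvent_fraction Crystal solvent content.
#' @return Mean phase error in degrees.
#' @export
calibrate_start_error <- function(true_phases, degraded, data,
                                  solvent_fraction) {
  assets <- template_assets(degraded, attr(data, "d_min"), solvent_fraction,
                            solvent = bulk_solvent_params(k_sol = 0),
                            histogram_offset = NULL, data = data)
  mean_phase_error(true_phases, assets$sf_start, data)
}

#' Find a template degradation landing in a starting-error band
#'
#' Bisects the coordinate-noise RMSD in \[0, 10\] A until the starting phase
#' error of the degraded template lies in `band` (tolerance 3 degrees on the
#' band edges). The start error grows monotonically with the RMSD up to
#' jitter, so bisection converges quickly.
#'
#' @param crystal Output of [make_toy_crystal()].
#' @param band Target start-error band in degrees (default c(65, 75)).
#' @param trim_fraction Residue-deletion fraction (default 0.3).
#' @param seed Seed for the degradation.
#' @return List with `template` (degraded model), `rmsd`, `start_error` and
#'   `assets` (the [template_assets()] of the returned template, computed
#'   without bulk solvent and with the template's natural density contrast,
#'   matching the toy crystal's vacuum solvent).
#' @export
degrade_to_error <- function(crystal, band = c(65, 75), trim_fraction = 0.3,
                             seed = 1) {
  target <- mean(band)
  sf <- crystal$true_phases; data <- crystal$data
  solvent <- crystal$spec$solvent_fraction
  err_at <- function(rmsd) {
    deg <- degrade_template(crystal$model, rmsd, trim_fraction, seed)
    list(deg = deg, err = calibrate_start_error(sf, deg, data, solvent))
  }
  lo <- 0; hi <- 10
  e_hi <- err_at(hi)
  if (e_hi$err < band[1] - 3)
    stop("requested start-error band unreachable within rmsd <= 10 A")
  best <- NULL
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    e <- err_at(mid)
    best <- c(e, rmsd = mid)
    if (e$err >= band[1] && e$err <= band[2]) break
    if (e$err < target) lo <- mid else hi <- mid
  }
  if (best$err < band[1] - 3 || best$err > band[2] + 3)
    stop("bisection failed to land in the requested start-error band")
  list(template = best$deg, rmsd = best$rmsd, start_error = best$err,
       assets = template_assets(best$deg, attr(data, "d_min"), solvent,
                                solvent = bulk_solvent_params(k_sol = 0),
                                histogram_offset = NULL, data = data))
}
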