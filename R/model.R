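# electron counts for the elements we expect in protein models
.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                MG = 12, NA. = 11, K = 19, CA = 20, MN = 25, FE = 26,
                CO = 27, NI = 28, CU = 29, ZN = 30, SE = 34)

element_electrons <- function(elem) {
  z <- .element_z[toupper(trimws(elem))]
  z[is.na(z)] <- 6  # unknown elements fall back to carbon
  unname(z)
}

#' Atomic model
#'
#' A collection of point atoms in a unit cell. Positions are Cartesian
#' Angstrom; each atom carries an electron count, occupancy and isotropic
#' temperature factor.
#'
#' @param cell A [unit_cell()].
#' @param atoms Data frame with columns `x`, `y`, `z`, and optionally `elem`
#'   (element symbol, default C), `z_elec` (electron count, derived from
#'   `elem` if absent), `occ` (default 1) and `b` (isotropic B, A^2,
#'   default 20).
#' @return Object of class `atomic_model`.
#' @export
atomic_model <- function(cell, atoms) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$elem)) atoms$elem <- "C"
  if (is.null(atoms$z_elec)) atoms$z_elec <- element_electrons(atoms$elem)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 20
  if (any(atoms$z_elec <= 0)) stop("electron counts must be positive")
  if (any(atoms$b <= 0)) stop("temperature factors must be positive")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0,1]")
  structure(list(cell = cell, atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model  %d atoms  <B> = %.1f A^2  %.0f electrons\n",
              nrow(x$atoms), mean(x$atoms$b), sum(x$atoms$occ * x$atoms$z_elec)))
  print(x$cell)
  invisible(x)
}

#' Electron density from an atomic model
#'
#' Each atom contributes a periodic isotropic Gaussian of total integral
#' occupancy * Z electrons. The Gaussian variance per Cartesian dimension is
#' B/(8 pi^2) plus an anti-aliasing floor of (0.8 * max grid spacing)^2,
#' which keeps the discrete cell integral equal to the electron count to
#' better than 0.1%. This single-Gaussian atom shape is a deliberate
#' simplification: the engine needs plausible density and phases at the
#' working resolution, not scattering-accurate form factors.
#'
#' @param model An [atomic_model()].
#' @param dims Grid divisions.
#' @param b_override Optional B value replacing every atom's B.
#' @return A [density_map()].
#' @export
model_to_density <- function(model, dims, b_override = NULL) {
  cell <- model$cell
  at <- model$atoms
  if (!is.null(b_override)) at$b <- b_override
  if (any(at$b <= 0)) stop("non-positive temperature factor")
  m <- frac_to_cart(cell)
  minv <- solve(m)
  spacing <- max(c(cell$a, cell$b, cell$c) / dims)
  s2_floor <- (0.8 * spacing)^2
  rho <- array(0, dims)
  frac <- t(minv %*% t(as.matrix(at[, c("x", "y", "z")]))) %% 1
  # per-axis fractional reach of a Cartesian radius (rows of M^-1)
  reach_scale <- sqrt(rowSums(minv^2))
  for (i in seq_len(nrow(at))) {
    s2 <- at$b[i] / (8 * pi^2) + s2_floor
    amp <- at$occ[i] * at$z_elec[i] / (2 * pi * s2)^1.5
    rcut <- 5 * sqrt(s2)
    nf <- pmin(ceiling(reach_scale * rcut * dims) + 1L, floor((dims - 1) / 2))
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
    g <- amp * exp(-(x^2 + y^2 + z^2) / (2 * s2))
    rho[(i1 %% dims[1]) + 1, (i2 %% dims[2]) + 1, (i3 %% dims[3]) + 1] <-
      rho[(i1 %% dims[1]) + 1, (i2 %% dims[2]) + 1, (i3 %% dims[3]) + 1] + g
  }
  density_map(rho, cell)
}

#' Flat bulk-solvent parameters
#'
#' @param k_sol Solvent density level (e/A^3, default 0.35).
#' @param b_sol Solvent smearing B (A^2); defaults to the model's mean B so
#'   the solvent temperature factor is consistent with the model.
#' @export
bulk_solvent_params <- function(k_sol = 0.35, b_sol = NULL) {
  stopifnot(k_sol >= 0, is.null(b_sol) || b_sol > 0)
  structure(list(k_sol = k_sol, b_sol = b_sol), class = "bulk_solvent_params")
}

#' Structure factors from an atomic model with flat bulk-solvent correction
#'
#' F_total(h) = F_atoms(h) + k_sol * exp(-B_sol |s|^2 / 4) * F_mask(h), where
#' F_mask is the transform of the solvent-region indicator (the complement of
#' the loose mask) and F_atoms comes from [model_to_density()] +
#' [map_to_sf()].
#'
#' @param model An [atomic_model()].
#' @param d_min Resolution cutoff (A).
#' @param dims Grid divisions; default from [grid_for_resolution()].
#' @param solvent [bulk_solvent_params()]; `k_sol = 0` disables the
#'   correction.
#' @param loose_mask [mask_grid()] delineating the protein region; required
#'   when `k_sol > 0`.
#' @param b_override Optional B override passed to [model_to_density()].
#' @return An [sf_set()].
#' @export
model_to_sf <- function(model, d_min, dims = NULL,
                        solvent = bulk_solvent_params(k_sol = 0),
                        loose_mask = NULL, b_override = NULL) {
  if (is.null(dims)) dims <- grid_for_resolution(model$cell, d_min)
  rho <- model_to_density(model, dims, b_override = b_override)
  sf <- map_to_sf(rho, d_min)
  if (solvent$k_sol > 0) {
    if (is.null(loose_mask)) stop("bulk solvent correction requires a loose mask")
    b_sol <- if (is.null(solvent$b_sol)) mean(model$atoms$b) else solvent$b_sol
    ind <- density_map(array(as.numeric(!loose_mask$values), dims), model$cell)
    fm <- map_to_sf(ind, d_min)
    idx <- match_hkl(sf, fm)
    damp <- exp(-b_sol / (4 * sf$d^2))
    sf$f <- sf$f + solvent$k_sol * damp * fm$f[idx]
  }
  sf
}

#' Shift temperature factors to a target mean
#'
#' All B values are shifted additively so the mean equals `target_mean`;
#' values driven below 2 A^2 are clamped there and the shift is re-applied
#' (up to a 5% tolerance on the final mean).
#'
#' @param model An [atomic_model()].
#' @param target_mean Target mean B (A^2, > 0).
#' @return The adjusted [atomic_model()].
#' @export
normalize_b_factors <- function(model, target_mean = 50) {
  stopifnot(target_mean > 0)
  b <- model$atoms$b
  for (it in 1:10) {
    b <- pmax(b + (target_mean - mean(b)), 2)
    if (abs(mean(b) - target_mean) <= 0.05 * target_mean) break
  }
  model$atoms$b <- b
  model
}

#' Read an atomic model from a PDB file
#'
#' Uses bio3d for parsing; the unit cell is taken from the CRYST1 record
#' unless supplied.
#'
#' @param path PDB file path.
#' @param cell Optional [unit_cell()] overriding CRYST1.
#' @return An [atomic_model()].
#' @export
read_pdb_model <- function(path, cell = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(cell)) {
    ln <- grep("^CRYST1", readLines(path), value = TRUE)
    if (!length(ln)) stop("no CRYST1 record; supply `cell`")
    cr <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                       substr(ln[1], 25, 33), substr(ln[1], 34, 40),
                       substr(ln[1], 41, 47), substr(ln[1], 48, 54)))
    if (anyNA(cr)) stop("malformed CRYST1 record")
    cell <- unit_cell(cr[1], cr[2], cr[3], cr[4], cr[5], cr[6])
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  atomic_model(cell, data.frame(
    x = at$x, y = at$y, z = at$z, elem = elem,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b) | at$b <= 0, 20, at$b)))
}

#' Write an atomic model as a minimal PDB file
#'
#' Emits CRYST1 (space group P 1) and ATOM records; atoms are written as
#' single-residue pseudo-atoms, which is sufficient for round-tripping
#' synthetic models and for inspection in standard viewers.
#'
#' @param model An [atomic_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_model <- function(model, path) {
  cl <- model$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  at <- model$atoms
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, substr(at$elem[i], 1, 3), "UNK", ((i - 1) %/% 50) + 1,
      at$x[i], at$y[i], at$z[i], at$occ[i], at$b[i],
      toupper(substr(at$elem[i], 1, 2))))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
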