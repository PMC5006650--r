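#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (Angstrom) and
#' angles (degrees). The metric must be positive definite (volume > 0).
#'
#' @param a,b,c Cell edge lengths in Angstrom, all > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(30, 30, 30)
#' unit_cell(7, 9, 11, 80, 95, 100)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (!all(c(a, b, c) > 0))
    stop("cell edges must be positive")
  if (!all(c(alpha, beta, gamma) > 0 & c(alpha, beta, gamma) < 180))
    stop("cell angles must lie in (0, 180) degrees")
  cl <- structure(list(a = a, b = b, c = c,
                       alpha = alpha, beta = beta, gamma = gamma),
                  class = "unit_cell")
  if (!is.finite(cell_volume(cl)) || cell_volume(cl) <= 0)
    stop("cell metric is not positive definite (volume <= 0)")
  cl
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Columns are the cell basis vectors in the standard PDB convention
#' (a along x, b in the xy plane), so `M %*% x_frac` gives Cartesian Angstrom.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
frac_to_cart <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3, ncol = 3)
}

#' Unit-cell volume in cubic Angstrom
#' @param cell A [unit_cell()].
#' @export
cell_volume <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  cell$a * cell$b * cell$c *
    sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Reciprocal metric tensor
#'
#' G* = (t(M) M)^-1 where M is the orthogonalization matrix; the d-spacing of
#' reflection h is 1/sqrt(h' G* h).
#'
#' @param cell A [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
reciprocal_metric <- function(cell) {
  m <- frac_to_cart(cell)
  solve(t(m) %*% m)
}

#' Resolution (d-spacing) of reflections
#'
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller indices.
#' @param cell A [unit_cell()].
#' @return d in Angstrom (vector of length n). The (0,0,0) index has no
#'   defined resolution and raises an error.
#' @examples
#' resolution_of(c(1, 0, 0), unit_cell(10, 10, 10))  # 10 A
#' @export
resolution_of <- function(hkl, cell) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  hkl <- as.matrix(hkl)
  if (any(rowSums(hkl != 0) == 0))
    stop("resolution undefined for the (0,0,0) index")
  gs <- reciprocal_metric(cell)
  s2 <- rowSums((hkl %*% gs) * hkl)
  1 / sqrt(s2)
}

# smallest integer >= n whose prime factors are all <= 7 (FFT-friendly)
fft_friendly <- function(n) {
  n <- as.integer(max(1L, ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Grid dimensions for a target resolution
#'
#' Chooses FFT-friendly divisions (prime factors <= 7) along each cell axis so
#' that the sampling interval edge/n is at most `d_min / oversample`.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution cutoff in Angstrom (> 0).
#' @param oversample Oversampling factor (>= 2; default 3).
#' @return Integer vector `c(n1, n2, n3)`.
#' @export
grid_for_resolution <- function(cell, d_min, oversample = 3) {
  stopifnot(d_min > 0, oversample >= 2)
  edges <- c(cell$a, cell$b, cell$c)
  vapply(edges, function(e) fft_friendly(e * oversample / d_min), integer(1))
}

#' Symmetry operator
#'
#' A rotation-part matrix `R` (acting on fractional coordinates, x' = R x + t)
#' and fractional translation `t`.
#'
#' @param rot 3x3 integer-valued matrix.
#' @param trans Fractional translation vector of length 3.
#' @export
sym_op <- function(rot, trans = c(0, 0, 0)) {
  rot <- matrix(as.numeric(rot), 3, 3)
  structure(list(rot = rot, trans = as.numeric(trans)), class = "sym_op")
}

#' Expand a reflection set to P1
#'
#' Applies each symmetry operator to every reflection (h' = h R), reduces to
#' the unique Friedel hemisphere and checks amplitude consistency among
#' symmetry mates. If the set carries a `phase` column (degrees), mate phases
#' are shifted by -360 * (h . t) per the phase-shift theorem.
#'
#' @param data A [reflection_set()].
#' @param ops List of [sym_op()]; must contain the identity.
#' @param tol Relative amplitude tolerance among symmetry mates.
#' @return A [reflection_set()] covering the P1 unique hemisphere.
#' @export
expand_to_p1 <- function(data, ops, tol = 1e-4) {
  has_id <- any(vapply(ops, function(o)
    all(abs(o$rot - diag(3)) < 1e-9) && all(abs(o$trans %% 1) < 1e-9), logical(1)))
  if (!has_id) stop("operator list must include the identity")
  cell <- attr(data, "cell")
  pieces <- lapply(ops, function(op) {
    hkl <- as.matrix(data[, c("h", "k", "l")]) %*% op$rot
    out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                      f_obs = data$f_obs, sigma = data$sigma,
                      status = data$status, stringsAsFactors = FALSE)
    if (!is.null(data$phase))
      out$phase <- (data$phase - 360 * as.matrix(data[, c("h", "k", "l")]) %*% op$trans) %% 360
    out
  })
  all <- do.call(rbind, pieces)
  # fold onto the standard hemisphere: Friedel mate has conjugate phase
  flip <- !hemisphere_side(all$h, all$k, all$l)
  all$h[flip] <- -all$h[flip]; all$k[flip] <- -all$k[flip]; all$l[flip] <- -all$l[flip]
  if (!is.null(all$phase)) all$phase[flip] <- (-all$phase[flip]) %% 360
  key <- paste(all$h, all$k, all$l)
  sp <- split(seq_len(nrow(all)), key)
  keep <- vapply(sp, function(idx) {
    fo <- all$f_obs[idx]
    fo <- fo[!is.na(fo)]
    if (length(fo) > 1 && diff(range(fo)) > tol * max(max(fo), 1e-12))
      stop(sprintf("inconsistent amplitudes among symmetry mates of (%d %d %d)",
                   all$h[idx[1]], all$k[idx[1]], all$l[idx[1]]))
    idx[1]
  }, integer(1))
  uniq <- all[sort(keep), , drop = FALSE]
  rownames(uniq) <- NULL
  reflection_set(hkl = uniq[, c("h", "k", "l")], f_obs = uniq$f_obs,
                 cell = cell, d_min = attr(data, "d_min"),
                 sigma = uniq$sigma, status = uniq$status,
                 phase = uniq$phase)
}

# TRUE for indices on the standard hemisphere (h>0, or h==0 & k>0, or h==k==0 & l>0)
hemisphere_side <- function(h, k, l) {
  h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0)
}
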