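#' Phasing run configuration
#'
#' Defaults follow the reference protocol: feedback epsilon 0.9 throughout;
#' kernel radius decreasing linearly from 3 to 2 A for template starts (4 to
#' 2 A for random starts); solvent clamp held at +/-1.0 e/A^3 for
#' `clamp_plateau` cycles, then ramped geometrically to `final_clamp`
#' (+/-0.01 e/A^3) over `clamp_window` cycles as HIO is slowly turned off;
#' about 2% of the observed reflections held out for the free R factor.
#'
#' @param total_cycles Number of iteration cycles.
#' @param epsilon HIO feedback coefficient (0, 1].
#' @param sigma_start,sigma_end Weighting-kernel radius schedule (A); if
#'   `sigma_start` is NULL it defaults to 3 for template starts and 4 for
#'   random starts.
#' @param clamp_plateau Last cycle of the full-clamp plateau (default 200).
#' @param clamp_window Length of the clamp turn-off ramp (default 200).
#' @param final_clamp,initial_clamp Solvent clamp bounds (e/A^3).
#' @param solvent_fraction Crystal solvent content in (0, 1).
#' @param looseness Extra mask volume fraction beyond 1 - solvent content
#'   (default 0.05, capped at 0.08).
#' @param free_fraction Fraction of observed reflections flagged free
#'   (default 0.02; 0 disables flagging).
#' @param n_low_res_replaced Number of lowest-resolution observed reflections
#'   replaced by calculated values; NULL flags all with d > 25 A.
#' @param start_mode "template" or "random".
#' @param seed Integer seed controlling the free set and random phases.
#' @param oversample Grid oversampling factor (default 3).
#' @param d_min_extend Factor < 1 applied to the data's d_min to set the
#'   iteration's resolution cutoff (default 0.9): the iteration runs at
#'   somewhat higher resolution than the observed data, with the extra
#'   reflections treated as missing (kept calculated and updated each
#'   cycle), so density modification has spectral headroom beyond the
#'   measured sphere. Set to 1 to disable.
#' @param histogram_matching Apply histogram matching inside the mask when a
#'   reference histogram is available (default TRUE).
#' @return Object of class `phasing_config`.
#' @export
phasing_config <- function(total_cycles = 500, epsilon = 0.9,
                           sigma_start = NULL, sigma_end = 2,
                           clamp_plateau = 200, clamp_window = 200,
                           final_clamp = 0.01, initial_clamp = 1.0,
                           solvent_fraction = 0.5, looseness = 0.05,
                           free_fraction = 0.02, n_low_res_replaced = NULL,
                           start_mode = c("template", "random"), seed = 1,
                           oversample = 3, histogram_matching = TRUE,
                           d_min_extend = 0.9) {
  start_mode <- match.arg(start_mode)
  if (is.null(sigma_start)) sigma_start <- if (start_mode == "random") 4 else 3
  stopifnot(epsilon > 0, epsilon <= 1, total_cycles >= 1,
            solvent_fraction > 0, solvent_fraction < 1,
            final_clamp > 0, initial_clamp >= final_clamp,
            free_fraction >= 0, free_fraction < 0.5)
  if (clamp_plateau >= total_cycles) clamp_window <- 0
  structure(list(total_cycles = total_cycles, epsilon = epsilon,
                 sigma_start = sigma_start, sigma_end = sigma_end,
                 clamp_plateau = clamp_plateau, clamp_window = clamp_window,
                 final_clamp = final_clamp, initial_clamp = initial_clamp,
                 solvent_fraction = solvent_fraction,
                 looseness = min(looseness, 0.08),
                 free_fraction = free_fraction,
                 n_low_res_replaced = n_low_res_replaced,
                 start_mode = start_mode, seed = seed,
                 oversample = oversample,
                 histogram_matching = histogram_matching,
                 d_min_extend = d_min_extend),
            class = "phasing_config")
}

# wrap phase differences (degrees) into [-180, 180)
wrap_phase <- function(dphi) ((dphi + 180) %% 360) - 180

#' Amplitude-weighted mean phase error
#'
#' Mean absolute phase difference between two structure-factor sets over
#' their common (measured) reflections, each difference wrapped into
#' \[0, 180\] degrees and weighted by the observed amplitude:
#' \deqn{\langle\Delta\phi\rangle = \sum f_{obs} |\Delta\phi| / \sum f_{obs}.}
#'
#' @param reference Reference [sf_set()] (e.g. phases of the deposited target
#'   model).
#' @param current Current [sf_set()].
#' @param weights Optional [reflection_set()] supplying f_obs weights (only
#'   its measured reflections enter), or a numeric vector aligned with
#'   `reference`; equal weights if NULL.
#' @return Mean phase error in degrees, in \[0, 180\].
#' @export
mean_phase_error <- function(reference, current, weights = NULL) {
  idx <- match_hkl(reference, current)
  ok <- !is.na(idx)
  if (inherits(weights, "refl_set")) {
    w <- weights$f_obs[match_hkl(reference, weights)]
    ok <- ok & !is.na(w)
  } else if (is.null(weights)) {
    w <- rep(1, nrow(reference))
  } else w <- weights
  if (!any(ok)) stop("no common reflections between the two sets")
  dphi <- abs(wrap_phase((Arg(reference$f[ok]) - Arg(current$f[idx[ok]])) * 180 / pi))
  sum(w[ok] * dphi) / sum(w[ok])
}

#' Free R factor
#'
#' R over the held-out free set with a least-squares scale k applied to the
#' calculated amplitudes:
#' \deqn{R_{free} = \sum_{free} |f_{obs} - k |F_c|| / \sum_{free} f_{obs}.}
#'
#' @param current [sf_set()] (or complex vector aligned with `data`).
#' @param data A [reflection_set()] with a nonempty free set.
#' @return R_free.
#' @export
r_free <- function(current, data) {
  fr <- which(data$status == "free")
  if (length(fr) == 0) stop("empty free set")
  f <- if (inherits(current, "sf_set")) current$f[match_hkl(data, current)] else current
  amp <- Mod(f[fr]); fo <- data$f_obs[fr]
  k <- sum(fo * amp) / sum(amp^2)
  sum(abs(fo - k * amp)) / sum(fo)
}

#' Convergence detection from the free R trace
#'
#' A convergent run announces itself by a sudden drop of the free R value,
#' while R_free of a failed run stays roughly constant. Returns the first
#' cycle where R_free decreased by at least `drop` over the preceding
#' `window` cycles and then stays below its pre-drop minimum for the rest of
#' the trace; NA if no such cycle exists. The first `burn_in` cycles are
#' ignored so the initial settling transient does not register as a drop.
#'
#' @param trace Numeric R_free series, or a trace data frame with an `r_free`
#'   column.
#' @param window Comparison window in cycles (default 100).
#' @param drop Required decrease (default 0.08).
#' @param burn_in Cycles excluded at the start (default 0; the pre-drop
#'   minimum then includes the starting level, which suppresses false
#'   positives from the settling transient).
#' @return Cycle index or NA.
#' @export
detect_convergence <- function(trace, window = 100, drop = 0.08,
                               burn_in = 0) {
  x <- if (is.data.frame(trace)) trace$r_free else as.numeric(trace)
  n <- length(x)
  if (n <= window + burn_in) return(NA_integer_)
  for (t in (window + burn_in + 1):n) {
    if (x[t - window] - x[t] >= drop) {
      pre_min <- min(x[(burn_in + 1):(t - window)])
      if (all(x[t:n] < pre_min)) return(t)
    }
  }
  NA_integer_
}

#' Map-vs-model correlation
#'
#' Pearson correlation over all voxels between a density map and the density
#' computed from an atomic model on the same grid.
#'
#' @param map A [density_map()].
#' @param model An [atomic_model()].
#' @param b_override Optional B override for the model density.
#' @return Correlation in \[-1, 1\].
#' @export
map_model_cc <- function(map, model, b_override = NULL) {
  md <- model_to_density(model, dim(map$values), b_override = b_override)
  a <- as.vector(map$values); b <- as.vector(md$values)
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance map")
  cor(a, b)
}

# Origin/enantiomorph alignment: finds the grid translation (and optional
# inversion) of `current` that best matches `reference` in the
# amplitude^2-weighted phase-correlation sense, then reports the exact
# weighted mean phase error there. In P1 an ab initio solution is only
# defined up to an origin shift and hand, so raw phase error against the
# truth is meaningless without this search.
aligned_phase_error <- function(reference, current, data, dims,
                                allow_inversion = TRUE) {
  idx <- match_hkl(reference, current)
  ok <- !is.na(idx) & !is.na(data$f_obs[match_hkl(reference, data)])
  hkl <- as.matrix(reference[ok, c("h", "k", "l")])
  w <- data$f_obs[match_hkl(reference, data)][ok]
  fr <- reference$f[ok]; fc <- current$f[idx[ok]]
  ip <- hkl_linear_index(hkl, dims); im <- hkl_linear_index(-hkl, dims)
  best <- Inf
  for (s in if (allow_inversion) c(1, -1) else 1) {
    phc <- s * Arg(fc)
    a <- array(0 + 0i, dims)
    z <- w^2 * exp(1i * (Arg(fr) - phc))
    a[ip] <- z; a[im] <- Conj(z)
    tt <- Re(fft(a))
    t0 <- (arrayInd(which.max(tt), dims) - 1) / dims
    dphi <- abs(wrap_phase((Arg(fr) - phc - 2 * pi * as.vector(hkl %*% as.numeric(t0))) * 180 / pi))
    err <- sum(w * dphi) / sum(w)
    if (err < best) best <- err
  }
  best
}

#' Run the iterative transform phasing loop
#'
#' Executes, per cycle: Fourier magnitude projection onto the observed
#' amplitudes (missing/free/low-res reflections keep calculated values) ->
#' inverse transform -> weighted-average mask update (kernel radius from the
#' linear sigma schedule) -> histogram matching inside the mask -> HIO
#' negative-feedback update outside the mask (clamp from the clamp schedule)
#' -> forward transform. Deterministic given the configuration seed.
#'
#' @param data A [reflection_set()]. Free and low-res-replacement flags are
#'   assigned from the config if not already present.
#' @param config A [phasing_config()].
#' @param start_phases [sf_set()] of starting phases (required for
#'   `start_mode = "template"`; ignored for random starts). Its amplitudes
#'   are only used for reflections without observed data.
#' @param assets Optional list with elements `loose_mask` ([mask_grid()]) and
#'   `ref_histogram` ([reference_histogram()]), e.g. from
#'   [template_assets()]. Histogram matching is skipped when no reference
#'   histogram is supplied.
#' @param reference_phases Optional [sf_set()] of ground-truth phases; when
#'   given, the per-cycle mean phase error is recorded in the trace.
#' @param align_reference If TRUE the phase error is minimized over origin
#'   translations (and inversion) before reporting - required for scoring
#'   random-start runs in P1, where the origin is arbitrary.
#' @param verbose Print a progress line every 50 cycles.
#' @return Object of class `hio_result`: list with `map` (final
#'   [density_map()]), `sf` (final [sf_set()]), `mask` (final [mask_grid()]),
#'   `trace` (data frame: cycle, sigma, epsilon, clamp, r_free,
#'   phase_error),
#'   `convergence_cycle`, `data` (the flagged reflection set) and `config`.
#' @export
run_phasing <- function(data, config, start_phases = NULL, assets = NULL,
                        reference_phases = NULL, align_reference = FALSE,
                        verbose = FALSE) {
  if (!any(data$status != "missing")) stop("no observed reflections")
  cell <- attr(data, "cell")
  d_min <- attr(data, "d_min")
  d_iter <- d_min * config$d_min_extend
  dims <- grid_for_resolution(cell, d_iter, config$oversample)
  v <- cell_volume(cell); nvox <- prod(dims)

  if (!any(data$status == "free") && config$free_fraction > 0)
    data <- assign_free_set(data, config$free_fraction, config$seed)
  if (!any(data$status == "low_res_replaced"))
    data <- select_low_res_replacement(data, config$n_low_res_replaced)
  if (d_iter < d_min) {
    # iterate at somewhat higher resolution than the observed cutoff; the
    # shell between d_iter and d_min is carried as missing (calculated)
    gh <- grid_hkl(dims)
    keep <- hemisphere_side(gh[, 1], gh[, 2], gh[, 3]) &
      abs(gh[, 1]) < dims[1] / 2 & abs(gh[, 2]) < dims[2] / 2 &
      abs(gh[, 3]) < dims[3] / 2
    gh <- gh[keep, , drop = FALSE]
    gd <- resolution_of(gh, cell)
    shell <- gd >= d_iter - 1e-9 & !(paste(gh[, 1], gh[, 2], gh[, 3]) %in%
                                       paste(data$h, data$k, data$l))
    if (any(shell)) {
      add <- data.frame(h = gh[shell, 1], k = gh[shell, 2], l = gh[shell, 3],
                        f_obs = NA_real_, sigma = NA_real_, d = gd[shell],
                        status = "missing", stringsAsFactors = FALSE)
      ext <- rbind(as.data.frame(data)[, names(add)], add)
      data <- reflection_set(as.matrix(ext[, c("h", "k", "l")]), ext$f_obs,
                             cell, d_iter, sigma = ext$sigma,
                             status = ext$status)
    }
  }

  hkl <- as.matrix(data[, c("h", "k", "l")])
  ip <- hkl_linear_index(hkl, dims)
  im <- hkl_linear_index(-hkl, dims)
  impose <- data$status == "observed"
  free_idx <- which(data$status == "free")
  meas <- !is.na(data$f_obs)

  # starting structure factors
  if (config$start_mode == "random") {
    set.seed(config$seed)
    amp0 <- data$f_obs
    amp0[is.na(amp0)] <- median(data$f_obs, na.rm = TRUE)
    f <- amp0 * exp(2i * pi * runif(nrow(data)))
  } else {
    if (is.null(start_phases)) stop("template start requires start_phases")
    idx <- match_hkl(data, start_phases)
    if (any(is.na(idx) & data$status != "missing"))
      stop("start_phases does not cover every measured reflection")
    f <- rep(0 + 0i, nrow(data))
    f[!is.na(idx)] <- start_phases$f[idx[!is.na(idx)]]
  }
  mod0 <- Mod(f)
  f[impose] <- data$f_obs[impose] * ifelse(mod0[impose] > 0, f[impose] / mod0[impose], 1 + 0i)

  # reference phases aligned to data rows (for the per-cycle error)
  ref_f <- NULL
  if (!is.null(reference_phases)) {
    ridx <- match_hkl(data, reference_phases)
    ref_f <- reference_phases$f[ridx]
  }

  protein_frac <- (1 - config$solvent_fraction) + config$looseness
  n_in <- max(1L, round(protein_frac * nvox))
  r2 <- grid_r2(cell, dims)
  hm_on <- config$histogram_matching && !is.null(assets$ref_histogram)
  if (hm_on) {
    ref <- assets$ref_histogram
    probs <- if (n_in > 1) (seq_len(n_in) - 1) / (n_in - 1) else 0.5
    hm_values <- quantile(ref$values, probs = probs, names = FALSE, type = 7)
  }
  sig_seq <- if (config$total_cycles > 1)
    seq(config$sigma_start, config$sigma_end, length.out = config$total_cycles)
  else config$sigma_start

  # build the starting input density; F(000) is unmeasured and floats freely
  # (kept calculated like a missing reflection) so that solvent flattening
  # toward zero and a positive protein region can coexist
  dc <- 0
  arr <- array(0 + 0i, dims)
  arr[ip] <- f; arr[im] <- Conj(f)
  rho_in <- Re(fft(arr)) / v
  f_calc <- f
  trace <- data.frame(cycle = seq_len(config$total_cycles), sigma = sig_seq,
                      epsilon = config$epsilon, clamp = NA_real_,
                      r_free = NA_real_, phase_error = NA_real_)
  mask <- NULL

  for (cy in seq_len(config$total_cycles)) {
    clamp <- clamp_schedule(cy, config$clamp_plateau, config$clamp_window,
                            config$final_clamp, config$initial_clamp)
    sigma <- sig_seq[cy]
    # magnitude projection, then back to real space
    f_proj <- f_calc
    modp <- Mod(f_proj)
    f_proj[impose] <- data$f_obs[impose] *
      ifelse(modp[impose] > 0, f_proj[impose] / modp[impose], 1 + 0i)
    arr[] <- 0 + 0i
    arr[ip] <- f_proj; arr[im] <- Conj(f_proj)
    arr[1] <- dc
    rho_proj <- Re(fft(arr)) / v
    # evolving mask from the weighted-average density
    ker <- exp(-r2 / (2 * sigma^2))
    ker[r2 > (3 * sigma)^2] <- 0
    wa <- Re(fft(fft(pmax(rho_proj, 0), inverse = TRUE) *
                   fft(ker, inverse = TRUE))) / (nvox * sum(ker))
    ord <- order(wa, decreasing = TRUE)
    inside <- ord[seq_len(n_in)]
    # protein region: histogram matching; solvent region: HIO feedback
    rho_new <- rho_proj
    if (hm_on) {
      vals <- rho_proj[inside]
      rho_new[inside[order(vals)]] <- hm_values
    }
    sol <- rep(TRUE, nvox); sol[inside] <- FALSE
    rho_new[sol] <- pmin(pmax(rho_in[sol] - config$epsilon * rho_proj[sol],
                              -clamp), clamp)
    # forward transform of the modified map
    farr <- fft(array(rho_new, dims), inverse = TRUE) * (v / nvox)
    f_calc <- farr[ip]
    dc <- Re(farr[1])
    # monitoring
    amp <- Mod(f_calc[free_idx]); fo <- data$f_obs[free_idx]
    ksc <- sum(fo * amp) / sum(amp^2)
    trace$clamp[cy] <- clamp
    trace$r_free[cy] <- if (length(free_idx)) sum(abs(fo - ksc * amp)) / sum(fo) else NA_real_
    if (!is.null(ref_f)) {
      if (align_reference) {
        cur <- sf_set(hkl, f_calc, cell, d = data$d)
        refset <- sf_set(hkl, ref_f, cell, d = data$d)
        trace$phase_error[cy] <- aligned_phase_error(refset, cur, data, dims)
      } else {
        dphi <- abs(wrap_phase((Arg(ref_f[meas]) - Arg(f_calc[meas])) * 180 / pi))
        trace$phase_error[cy] <- sum(data$f_obs[meas] * dphi) / sum(data$f_obs[meas])
      }
    }
    rho_in <- rho_new
    if (verbose && cy %% 50 == 0)
      message(sprintf("cycle %4d  sigma %.2f  clamp %.3g  Rfree %.3f  dphi %s",
                      cy, sigma, clamp, trace$r_free[cy],
                      ifelse(is.na(trace$phase_error[cy]), "-",
                             sprintf("%.1f", trace$phase_error[cy]))))
  }
  mask_arr <- array(FALSE, dims); mask_arr[inside] <- TRUE
  structure(list(
    map = density_map(array(rho_in, dims), cell),
    sf = sf_set(hkl, f_calc, cell, d = data$d),
    mask = mask_grid(mask_arr, cell),
    trace = trace,
    convergence_cycle = detect_convergence(trace$r_free),
    data = data, config = config), class = "hio_result")
}

#' @export
print.hio_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("HIO phasing result  %d cycles  final Rfree %.3f\n",
              n, x$trace$r_free[n]))
  if (!all(is.na(x$trace$phase_error)))
    cat(sprintf("  phase error: start %.1f deg -> final %.1f deg\n",
                x$trace$phase_error[1], x$trace$phase_error[n]))
  cat(sprintf("  convergence cycle: %s\n",
              ifelse(is.na(x$convergence_cycle), "none",
                     x$convergence_cycle)))
  invisible(x)
}

#' Starting assets from a placed template model
#'
#' Computes everything the engine needs from a placed (molecular-replacement)
#' template: starting structure factors with flat bulk-solvent correction,
#' the loose protein mask (1 A kernel) and the reference histogram for the
#' protein region (offset 0.05 e/A^3 above the solvent level).
#'
#' @param template An [atomic_model()] placed in the target cell.
#' @param d_min Resolution cutoff (A).
#' @param solvent_fraction Crystal solvent content.
#' @param looseness Loose-mask allowance (default 0.05, capped 0.08).
#' @param b_target Optional mean-B normalization target (e.g. 50 A^2); NULL
#'   keeps the model's B values.
#' @param solvent [bulk_solvent_params()] for the starting structure factors.
#' @param histogram_offset Protein-mean density above the solvent level for
#'   the reference histogram (e/A^3); NULL keeps the template's natural
#'   contrast (appropriate for synthetic crystals with empty solvent).
#' @param data Optional [reflection_set()]; when supplied, the template map
#'   is put on the observed-amplitude scale (least-squares scale factor
#'   between f_obs and the template amplitudes) before the reference
#'   histogram is extracted, so a template with missing atoms does not
#'   impose an under-scaled histogram.
#' @param oversample Grid oversampling factor.
#' @return List with `sf_start`, `loose_mask`, `ref_histogram`,
#'   `template_map`.
#' @export
template_assets <- function(template, d_min, solvent_fraction,
                            looseness = 0.05, b_target = NULL,
                            solvent = bulk_solvent_params(),
                            histogram_offset = 0.05, data = NULL,
                            oversample = 3) {
  if (!is.null(b_target)) template <- normalize_b_factors(template, b_target)
  dims <- grid_for_resolution(template$cell, d_min, oversample)
  tmap <- model_to_density(template, dims)
  lmask <- loose_model_mask(tmap, solvent_fraction, looseness)
  sf0 <- model_to_sf(template, d_min, dims = dims, solvent = solvent,
                     loose_mask = lmask)
  hmap <- tmap
  if (!is.null(data)) {
    idx <- match_hkl(data, sf0)
    ok <- !is.na(data$f_obs) & !is.na(idx)
    amp <- Mod(sf0$f[idx[ok]])
    k <- sum(data$f_obs[ok] * amp) / sum(amp^2)
    hmap <- density_map(tmap$values * k, tmap$cell)
  }
  list(sf_start = sf0, loose_mask = lmask,
       ref_histogram = reference_histogram(hmap, lmask, histogram_offset),
       template_map = tmap)
}
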