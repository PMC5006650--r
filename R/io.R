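# status <-> SF-mmCIF refln status codes
.status_to_code <- c(observed = "o", free = "f", missing = "x",
                     low_res_replaced = "l")
.code_to_status <- c(o = "observed", f = "free", x = "missing",
                     l = "low_res_replaced")

#' Write reflections as SF-mmCIF
#'
#' Emits a structure-factor mmCIF with the cell, the resolution cutoff and a
#' `_refln` loop (h, k, l, F_meas_au, sigma, status, and phase_calc when the
#' set carries a `phase` column). Missing reflections are written with `?`
#' amplitudes and status `x`; free reflections carry status `f`,
#' low-resolution-replaced ones status `l`.
#'
#' @param data A [reflection_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reflections <- function(data, path) {
  cell <- attr(data, "cell")
  fmt <- function(x) ifelse(is.na(x), "?", sprintf("%.6g", x))
  lines <- c(
    "data_hiophase",
    sprintf("_cell.length_a %.4f", cell$a),
    sprintf("_cell.length_b %.4f", cell$b),
    sprintf("_cell.length_c %.4f", cell$c),
    sprintf("_cell.angle_alpha %.4f", cell$alpha),
    sprintf("_cell.angle_beta %.4f", cell$beta),
    sprintf("_cell.angle_gamma %.4f", cell$gamma),
    sprintf("_reflns.d_resolution_high %.4f", attr(data, "d_min")),
    "loop_",
    "_refln.index_h",
    "_refln.index_k",
    "_refln.index_l",
    "_refln.F_meas_au",
    "_refln.F_meas_sigma_au",
    "_refln.status")
  if (is.null(data$phase)) {
    lines <- c(lines, sprintf("%d %d %d %s %s %s", data$h, data$k, data$l,
                              fmt(data$f_obs), fmt(data$sigma),
                              .status_to_code[data$status]))
  } else {
    lines <- c(lines[seq_len(length(lines) - 1)], "_refln.status",
               "_refln.phase_calc",
               sprintf("%d %d %d %s %s %s %s", data$h, data$k, data$l,
                       fmt(data$f_obs), fmt(data$sigma),
                       .status_to_code[data$status], fmt(data$phase)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read reflections from SF-mmCIF or TSV
#'
#' Parses the `_refln` loop of a structure-factor mmCIF (or a TSV with
#' columns h, k, l, f_obs, sigma, status). The amplitude column must be a
#' measured structure-factor amplitude; an intensity-only file raises an
#' explicit error rather than converting silently. Reflections inside the
#' resolution sphere that are absent from the file are enumerated as
#' `missing`, so completeness is accounted for.
#'
#' @param path Input path.
#' @param cell Optional [unit_cell()] (required for TSV without cell
#'   metadata; overrides the file for mmCIF).
#' @param d_min Optional resolution cutoff; defaults to the file's value or
#'   the highest-resolution reflection present.
#' @param enumerate_missing Add `missing` records for unobserved reflections
#'   inside the sphere (default TRUE).
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, cell = NULL, d_min = NULL,
                             enumerate_missing = TRUE) {
  lines <- readLines(path)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (is.null(cell)) stop("TSV input requires an explicit `cell`")
  } else {
    getnum <- function(tag) {
      ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
      if (!length(ln)) return(NA_real_)
      as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
    }
    if (is.null(cell)) {
      cp <- vapply(c("_cell.length_a", "_cell.length_b", "_cell.length_c",
                     "_cell.angle_alpha", "_cell.angle_beta",
                     "_cell.angle_gamma"), getnum, numeric(1))
      if (anyNA(cp)) stop("no cell metadata in file; supply `cell`")
      cp <- unname(cp)
      cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
    }
    if (is.null(d_min)) {
      dm <- getnum("_reflns.d_resolution_high")
      if (!is.na(dm)) d_min <- dm
    }
    loop_at <- grep("^loop_", lines)
    if (!length(loop_at)) stop("no loop_ block found")
    hdr_idx <- loop_at[1] + 1
    cols <- character(0)
    while (hdr_idx <= length(lines) && grepl("^_refln\\.", trimws(lines[hdr_idx]))) {
      cols <- c(cols, trimws(lines[hdr_idx])); hdr_idx <- hdr_idx + 1
    }
    if (!length(cols)) stop("no _refln columns found")
    fcol <- match("_refln.F_meas_au", cols)
    if (is.na(fcol)) {
      if ("_refln.intensity_meas" %in% cols)
        stop("intensity-only file: convert intensities to amplitudes explicitly")
      stop("no _refln.F_meas_au amplitude column found")
    }
    body <- lines[hdr_idx:length(lines)]
    body <- body[nzchar(trimws(body)) & !grepl("^(_|#|loop_|data_)", trimws(body))]
    toks <- strsplit(trimws(body), "\\s+")
    toks <- toks[lengths(toks) == length(cols)]
    mat <- do.call(rbind, toks)
    colnames(mat) <- cols
    num <- function(x) suppressWarnings(as.numeric(ifelse(x == "?", NA, x)))
    tab <- data.frame(
      h = as.integer(mat[, "_refln.index_h"]),
      k = as.integer(mat[, "_refln.index_k"]),
      l = as.integer(mat[, "_refln.index_l"]),
      f_obs = num(mat[, "_refln.F_meas_au"]),
      sigma = if ("_refln.F_meas_sigma_au" %in% cols)
        num(mat[, "_refln.F_meas_sigma_au"]) else NA_real_,
      status = if ("_refln.status" %in% cols)
        unname(.code_to_status[mat[, "_refln.status"]]) else NA_character_,
      stringsAsFactors = FALSE)
    if ("_refln.phase_calc" %in% cols)
      tab$phase <- num(mat[, "_refln.phase_calc"])
  }
  key <- paste(tab$h, tab$k, tab$l)
  if (anyDuplicated(key))
    stop("duplicate hkl in file: ", key[duplicated(key)][1])
  if (all(is.na(tab$status)))
    tab$status <- ifelse(is.na(tab$f_obs), "missing", "observed")
  d <- resolution_of(as.matrix(tab[, c("h", "k", "l")]), cell)
  if (is.null(d_min)) d_min <- min(d)
  if (enumerate_missing) {
    hmax <- floor(c(cell$a, cell$b, cell$c) / d_min) + 1
    grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                        l = -hmax[3]:hmax[3])
    grid <- grid[hemisphere_side(grid$h, grid$k, grid$l), ]
    gd <- resolution_of(as.matrix(grid), cell)
    grid <- grid[gd >= d_min - 1e-9, ]
    absent <- !(paste(grid$h, grid$k, grid$l) %in% key)
    if (any(absent)) {
      add <- data.frame(h = grid$h[absent], k = grid$k[absent],
                        l = grid$l[absent], f_obs = NA_real_,
                        sigma = NA_real_, status = "missing",
                        stringsAsFactors = FALSE)
      if (!is.null(tab$phase)) add$phase <- NA_real_
      tab <- rbind(tab[, names(add)], add)
    }
  }
  reflection_set(as.matrix(tab[, c("h", "k", "l")]), tab$f_obs, cell, d_min,
                 sigma = tab$sigma, status = tab$status, phase = tab$phase)
}

#' Write a density map (or mask) in CCP4/MRC format
#'
#' Mode-2 (float32) map with x fastest (MAPC/MAPR/MAPS = 1/2/3), matching
#' R's column-major array layout; masks are written as 0/1 voxels.
#'
#' @param map A [density_map()] or [mask_grid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ccp4_map <- function(map, path) {
  vals <- if (inherits(map, "mask_grid")) array(as.numeric(map$values), dim(map$values))
          else map$values
  cell <- map$cell
  dims <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                    # NC NR NS
  wi(2)                       # MODE float32
  wi(c(0, 0, 0))              # start
  wi(dims)                    # intervals
  wf(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1)                       # ISPG = P1
  wi(0)                       # NSYMBT
  wi(rep(0, 25))              # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)  # little-endian machine stamp
  wf(sd(as.vector(vals)))
  wi(1)                       # NLABL
  lab <- sprintf("%-80s", "hiophase density map")
  writeChar(paste0(lab, strrep(" ", 80 * 9)), con, nchars = 800, eos = NULL)
  wf(as.vector(vals))
  invisible(path)
}

#' Read a CCP4/MRC map
#'
#' Supports mode-2 maps; axis order is restored to x-fastest on read when the
#' file uses a permuted MAPC/MAPR/MAPS.
#'
#' @param path Input path.
#' @return A [density_map()].
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) maps supported")
  ri(3); nint <- ri(3)
  cp <- rf(6)
  axes <- ri(3)
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(dims))
  arr <- array(vals, dims)
  if (!identical(axes, 1:3)) aperm(arr, order(axes)) -> arr
  density_map(arr, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]))
}

#' Write the per-cycle iteration trace as CSV
#'
#' @param result An `hio_result` from [run_phasing()] (or its trace data
#'   frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(result, path) {
  tr <- if (is.data.frame(result)) result else result$trace
  write.table(tr, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record (configuration echo, seed, input digests, package version,
#' trace path) sufficient to reproduce a run.
#'
#' @param result An `hio_result`.
#' @param path Output path.
#' @param inputs Named character vector of input file paths to digest.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(result, path, inputs = character(0)) {
  digests <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  jsonlite::write_json(list(
    package = "hiophase",
    version = as.character(utils::packageVersion("hiophase")),
    config = unclass(result$config),
    seed = result$config$seed,
    inputs = digests,
    convergence_cycle = result$convergence_cycle,
    final_r_free = tail(result$trace$r_free, 1)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
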