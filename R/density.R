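# Density maps and map coefficients.
#
# A density_map carries the whole unit cell on a regular grid, interpreted
# periodically; grid node (i, j, k) (0-based) sits at fractional coordinate
# (i/nx, j/ny, k/nz). Minimal binary readers/writers for the CCP4/MRC map and
# MTZ reflection formats are implemented here (full-cell, P1, float data):
# no installed R package handles either format.

#' Construct a density map
#'
#' @param grid 3-D numeric array ordered \code{[x, y, z]} over the unit cell.
#' @param cell unit cell (lengths in angstroms, angles in degrees).
#' @param periodic logical; unit-cell maps are periodic.
#' @return object of class \code{density_map}.
#' @export
density_map <- function(grid, cell, periodic = TRUE) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (any(dim(grid) < 2)) stop("map grid needs at least 2 samples per axis")
  if (any(!is.finite(grid))) stop("map grid contains non-finite values")
  structure(list(grid = grid, cell = as_cell(cell), periodic = periodic),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_map: %d x %d x %d grid, cell %.2f %.2f %.2f A\n",
              d[1], d[2], d[3], x$cell$a, x$cell$b, x$cell$c))
  cat(sprintf("  mean %.4g  sd %.4g  periodic: %s\n", mean(x$grid),
              stats::sd(as.numeric(x$grid)), x$periodic))
  invisible(x)
}

#' Sigma-scale a map to zero mean and unit variance
#'
#' @param map a \code{density_map}.
#' @return the rescaled \code{density_map}.
#' @export
normalize_map <- function(map) {
  g <- map$grid
  mu <- mean(g)
  sdv <- sqrt(mean((g - mu)^2))
  if (sdv == 0) stop("map has zero variance; cannot sigma-scale")
  map$grid <- (g - mu) / sdv
  map
}

#' Read a density source: CCP4/MRC map or MTZ map coefficients
#'
#' MTZ input is converted to a real-space map by inverse Fourier synthesis of
#' the labelled amplitude/phase columns; the result is sigma-scaled.
#'
#' @param path a \code{.map}/\code{.mrc}/\code{.ccp4} or \code{.mtz} file.
#' @param labels optional \code{c(F, PHI)} column labels for MTZ input. When
#'   absent, the pairs (FWT, PHWT) and (2FOFCWT, PH2FOFCWT) are tried.
#' @return a normalized \code{density_map}.
#' @export
read_density <- function(path, labels = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtz") {
    co <- read_mtz(path, labels = labels)
    map_from_coefficients(co)
  } else if (ext %in% c("map", "mrc", "ccp4")) {
    normalize_map(read_ccp4_map(path))
  } else {
    stop("unrecognized density format '.", ext,
         "' (expected .map/.mrc/.ccp4 or .mtz)")
  }
}

## ---- CCP4/MRC maps ---------------------------------------------------------

#' Read a CCP4/MRC map covering a full unit cell
#'
#' Supports mode-2 (float) maps whose sampled block is the complete cell
#' (starts at 0, section counts equal the cell sampling); arbitrary axis
#' orderings are permuted to x, y, z.
#'
#' @param path map file.
#' @return a \code{density_map} (not normalized).
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cellv <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  axmap <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little"))
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 52 * 4)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop(basename(path), " is not a CCP4/MRC map (missing MAP stamp)")
  if (hdr_i[4] != 2L)
    stop("unsupported map mode ", hdr_i[4], " (only mode 2, float32)")
  seek(con, 1024 + nsymbt)
  nc <- hdr_i[1]; nr <- hdr_i[2]; ns <- hdr_i[3]
  vals <- readBin(con, "numeric", n = nc * nr * ns, size = 4,
                  endian = "little")
  if (length(vals) < nc * nr * ns) stop("truncated map data in ", path)
  arr <- array(vals, dim = c(nc, nr, ns))
  intervals <- hdr_i[8:10]
  starts <- hdr_i[5:7]
  if (any(starts != 0L) || any(c(nc, nr, ns) != intervals[axmap]))
    stop("only full-unit-cell maps are supported (starts 0, sizes = sampling)")
  arr <- aperm(arr, order(axmap))
  density_map(arr, as_cell(cellv), periodic = TRUE)
}

#' Write a density map as a CCP4 mode-2 map file
#'
#' @param map a \code{density_map}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_ccp4_map <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NC NR NS
  wi(2L)                      # MODE float32
  wi(c(0L, 0L, 0L))           # starts
  wi(d)                       # cell sampling
  wf(unlist(map$cell))        # cell
  wi(c(1L, 2L, 3L))           # axis order x,y,z
  g <- as.numeric(map$grid)
  wf(c(min(g), max(g), mean(g)))
  wi(1L)                      # ISPG = P1
  wi(0L)                      # NSYMBT
  wi(rep(0L, 27))             # unused words 25..51
  wi(0L)                      # word 52
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(sqrt(mean((g - mean(g))^2)))                   # RMS
  wi(0L)                                            # NLABL
  writeBin(raw(800), con)                           # labels
  wf(g)
  invisible(path)
}

## ---- MTZ reflection files --------------------------------------------------

#' Read amplitude/phase columns from an MTZ reflection file
#'
#' Minimal reader for merged MTZ files: the H, K, L columns plus one
#' amplitude/phase pair are extracted.
#'
#' @param path MTZ file.
#' @param labels optional \code{c(F, PHI)} labels; when absent the
#'   (FWT, PHWT) then (2FOFCWT, PH2FOFCWT) conventions are tried.
#' @return a \code{map_coefficients} object: list with \code{hkl} (n x 3
#'   integer matrix), \code{amplitude}, \code{phase} (degrees), \code{cell}
#'   and \code{labels}.
#' @export
read_mtz <- function(path, labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MTZ "))
    stop(basename(path), " is not an MTZ file")
  hdr_pos <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, (hdr_pos - 1) * 4)
  hdr_raw <- readBin(con, "raw", n = file.size(path) - (hdr_pos - 1) * 4)
  nrec <- length(hdr_raw) %/% 80
  recs <- vapply(seq_len(nrec), function(i)
    rawToChar(hdr_raw[((i - 1) * 80 + 1):(i * 80)]), character(1))
  recs <- trimws(recs)
  ncol_rec <- grep("^NCOL", recs, value = TRUE)
  if (length(ncol_rec) == 0) stop("MTZ header lacks NCOL record")
  nn <- as.numeric(strsplit(ncol_rec[1], "\\s+")[[1]][-1])
  ncol <- nn[1]; nref <- nn[2]
  cell_rec <- grep("^CELL", recs, value = TRUE)
  cellv <- as.numeric(strsplit(cell_rec[1], "\\s+")[[1]][2:7])
  col_recs <- grep("^COLUMN", recs, value = TRUE)
  col_labels <- vapply(strsplit(col_recs, "\\s+"), `[`, character(1), 2)
  col_types <- vapply(strsplit(col_recs, "\\s+"), `[`, character(1), 3)

  seek(con, 20 * 4)
  dat <- readBin(con, "numeric", n = ncol * nref, size = 4, endian = "little")
  m <- matrix(dat, nrow = nref, ncol = ncol, byrow = TRUE)
  colnames(m) <- col_labels

  need <- c("H", "K", "L")
  if (!all(need %in% col_labels))
    stop("MTZ lacks H K L columns; available: ",
         paste(col_labels, collapse = ", "))
  pair <- resolve_mtz_labels(col_labels, col_types, labels)
  hkl <- matrix(as.integer(round(m[, need])), ncol = 3,
                dimnames = list(NULL, need))
  if (anyDuplicated(apply(hkl, 1, paste, collapse = ",")))
    stop("duplicate Miller indices in ", basename(path))
  amp <- m[, pair[1]]
  if (any(amp < 0)) stop("negative amplitudes in column ", pair[1])
  structure(list(hkl = hkl, amplitude = amp, phase = m[, pair[2]],
                 cell = as_cell(cellv), labels = pair),
            class = "map_coefficients")
}

resolve_mtz_labels <- function(col_labels, col_types, labels) {
  if (!is.null(labels)) {
    if (length(labels) != 2)
      stop("labels must be c(F, PHI)")
    missing <- setdiff(labels, col_labels)
    if (length(missing))
      stop("column(s) ", paste(missing, collapse = ", "), " not in MTZ; ",
           "available: ", paste(col_labels, collapse = ", "))
    return(labels)
  }
  for (cand in list(c("FWT", "PHWT"), c("2FOFCWT", "PH2FOFCWT")))
    if (all(cand %in% col_labels)) return(cand)
  stop("no recognized amplitude/phase pair (tried FWT/PHWT, ",
       "2FOFCWT/PH2FOFCWT); available: ", paste(col_labels, collapse = ", "))
}

#' Write map coefficients to a minimal MTZ file
#'
#' @param coeffs a \code{map_coefficients} object (or list with \code{hkl},
#'   \code{amplitude}, \code{phase}, \code{cell}).
#' @param path output path.
#' @param labels amplitude/phase column labels to write.
#' @return invisibly, \code{path}.
#' @export
write_mtz <- function(coeffs, path, labels = c("FWT", "PHWT")) {
  hkl <- coeffs$hkl
  nref <- nrow(hkl)
  ncol <- 5L
  dat <- cbind(hkl[, 1], hkl[, 2], hkl[, 3], coeffs$amplitude, coeffs$phase)
  cell <- as_cell(coeffs$cell)
  rec <- function(s) formatC(s, width = 80, flag = "-")
  colrec <- function(lab, type, v)
    rec(sprintf("COLUMN %-30s %s %17.4f %17.4f    1", lab, type, min(v), max(v)))
  hdr <- c(
    rec("VERS MTZ:V1.1"),
    rec("TITLE seqregister map coefficients"),
    rec(sprintf("NCOL %8d %12d %8d", ncol, nref, 0L)),
    rec(sprintf("CELL  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
                cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)),
    rec("SORT    1   2   3   0   0"),
    rec("SYMINF   1  1 P     1            'P 1'   PG1"),
    rec("SYMM X,  Y,  Z"),
    rec("VALM NAN"),
    colrec("H", "H", hkl[, 1]), colrec("K", "H", hkl[, 2]),
    colrec("L", "H", hkl[, 3]),
    colrec(labels[1], "F", coeffs$amplitude),
    colrec(labels[2], "P", coeffs$phase),
    rec("END"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MTZ ", con, eos = NULL)
  hdr_pos <- 21L + ncol * nref
  writeBin(as.integer(hdr_pos), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  writeBin(raw((20 - 3) * 4), con)          # pad to data start at word 21
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  for (r in hdr) writeChar(r, con, nchars = 80, eos = NULL)
  invisible(path)
}

#' Synthesize a real-space map from Fourier map coefficients
#'
#' Computes \eqn{\rho(x) = (1/V) \sum_h F_h \exp(i\phi_h) \exp(-2\pi i h x)}
#' on a grid whose spacing is at most \code{d_min / oversampling} along each
#' cell edge, via FFT. Friedel mates are generated automatically.
#'
#' @param coeffs a \code{map_coefficients} object.
#' @param oversampling grid spacing divisor relative to the resolution limit
#'   (default 3, i.e. spacing \code{d_min/3}).
#' @param normalize sigma-scale the result (default \code{TRUE}).
#' @return a \code{density_map}.
#' @export
map_from_coefficients <- function(coeffs, oversampling = 3, normalize = TRUE) {
  cell <- as_cell(coeffs$cell)
  hkl <- coeffs$hkl
  d <- reflection_resolution(hkl, cell)
  d_min <- min(d)
  n <- vapply(seq_len(3), function(i) {
    len <- c(cell$a, cell$b, cell$c)[i]
    max(ceiling(len * oversampling / d_min), 2L * max(abs(hkl[, i])) + 1L)
  }, numeric(1))
  n <- as.integer(2 * ceiling(n / 2))  # even grid sizes
  z <- array(complex(real = 0, imaginary = 0), dim = n)
  f <- coeffs$amplitude * exp(1i * coeffs$phase * pi / 180)
  idx <- function(h, n) (h %% n) + 1L
  for (r in seq_len(nrow(hkl))) {
    h <- hkl[r, ]
    z[idx(h[1], n[1]), idx(h[2], n[2]), idx(h[3], n[3])] <-
      z[idx(h[1], n[1]), idx(h[2], n[2]), idx(h[3], n[3])] + f[r]
    if (any(h != 0)) {
      z[idx(-h[1], n[1]), idx(-h[2], n[2]), idx(-h[3], n[3])] <-
        z[idx(-h[1], n[1]), idx(-h[2], n[2]), idx(-h[3], n[3])] + Conj(f[r])
    }
  }
  # fft() computes sum z_h exp(-2*pi*i*h.x/n): crystallographic synthesis
  rho <- Re(stats::fft(z)) / cell_volume(cell)
  map <- density_map(rho, cell, periodic = TRUE)
  if (normalize) normalize_map(map) else map
}

# Resolution d (A) of each reflection from the reciprocal metric tensor.
reflection_resolution <- function(hkl, cell) {
  m <- orthogonalization_matrix(cell)
  astar <- t(solve(m))  # columns are reciprocal basis vectors
  s <- hkl %*% t(astar) # reciprocal-space vectors, 1/A
  inv_d <- sqrt(rowSums(s^2))
  ifelse(inv_d == 0, Inf, 1 / inv_d)
}

## ---- Interpolation ---------------------------------------------------------

#' Trilinear interpolation of a density map
#'
#' Periodic maps wrap across cell boundaries; interpolation is exact at grid
#' nodes.
#'
#' @param map a \code{density_map}.
#' @param xyz orthogonal angstrom coordinates: numeric vector of length 3 or
#'   an n x 3 matrix.
#' @return numeric vector of interpolated values.
#' @export
interpolate_map <- function(map, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  n <- dim(map$grid)
  frac <- xyz %*% t(solve(orthogonalization_matrix(map$cell)))
  if (!map$periodic &&
      (any(frac < 0) || any(frac >= 1)))
    stop("position outside non-periodic map bounds")
  g <- sweep(frac, 2, n, `*`)
  i0 <- floor(g)
  tt <- g - i0
  nx <- n[1]; ny <- n[2]
  lin <- function(ix, iy, iz) {
    ix <- ix %% n[1]; iy <- iy %% n[2]; iz <- iz %% n[3]
    map$grid[1 + ix + nx * (iy + ny * iz)]
  }
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tt[, 1] else 1 - tt[, 1]) *
         (if (dy) tt[, 2] else 1 - tt[, 2]) *
         (if (dz) tt[, 3] else 1 - tt[, 3])
    v <- v + w * lin(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
  }
  as.numeric(v)
}

## ---- Synthetic density -----------------------------------------------------

#' Simulate a density map from a model with Gaussian atoms
#'
#' Every atom contributes a unit-height isotropic Gaussian of width
#' \code{sigma}; the map emulates a blurred experimental map at roughly
#' \code{2.355 * sigma} angstrom full-width resolution. Restricted to
#' orthogonal cells (the synthetic generator only produces those), where the
#' Gaussian is separable along grid axes.
#'
#' @param model a \code{structure_model} with an orthogonal unit cell.
#' @param spacing target grid spacing in angstroms (default 0.8).
#' @param sigma Gaussian width in angstroms (default 1.0, roughly a 2.5 A
#'   resolution blur).
#' @param normalize sigma-scale the result (default \code{TRUE}).
#' @return a \code{density_map}.
#' @export
simulate_map <- function(model, spacing = 0.8, sigma = 1.0, normalize = TRUE) {
  cell <- model$cell
  if (any(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) > 1e-6))
    stop("simulate_map supports orthogonal cells only")
  len <- c(cell$a, cell$b, cell$c)
  n <- pmax(4L, as.integer(ceiling(len / spacing)))
  delta <- len / n
  grid <- array(0, dim = n)
  reach <- ceiling(3.5 * sigma / delta)
  for (ch in model$chains) for (r in ch$residues) {
    xyz <- r$atoms
    for (a in seq_len(nrow(xyz))) {
      p <- xyz[a, ]
      i0 <- round(p / delta)
      gauss1d <- function(ax) {
        ii <- (i0[ax] - reach[ax]):(i0[ax] + reach[ax])
        x <- ii * delta[ax] - p[ax]
        list(idx = (ii %% n[ax]) + 1L, w = exp(-x^2 / (2 * sigma^2)))
      }
      gx <- gauss1d(1); gy <- gauss1d(2); gz <- gauss1d(3)
      blk <- outer(outer(gx$w, gy$w), gz$w)
      grid[gx$idx, gy$idx, gz$idx] <- grid[gx$idx, gy$idx, gz$idx] + blk
    }
  }
  map <- density_map(grid, cell, periodic = TRUE)
  if (normalize && stats::sd(as.numeric(grid)) > 0) normalize_map(map) else map
}
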