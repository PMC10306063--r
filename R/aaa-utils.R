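# Shared constants and small helpers.

# Fixed one-letter alphabet; every probability matrix column follows this order.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
         G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
         M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

#' Convert three-letter residue names to one-letter codes
#'
#' Non-standard names (including \code{UNK}) map to \code{"X"}.
#'
#' @param type3 character vector of three-letter residue names.
#' @return character vector of one-letter codes.
#' @export
aa_three_to_one <- function(type3) {
  out <- AA3_TO_1[toupper(type3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Convert one-letter codes to three-letter residue names
#'
#' @param type1 character vector of one-letter codes; \code{"X"} maps to
#'   \code{UNK}.
#' @return character vector of three-letter names.
#' @export
aa_one_to_three <- function(type1) {
  out <- AA3[toupper(type1)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

#' Orthogonalization matrix of a crystallographic unit cell
#'
#' Standard PDB convention: a along x, b in the xy plane. Multiplying a
#' fractional coordinate column vector by this matrix gives orthogonal
#' angstroms; the inverse fractionalizes.
#'
#' @param cell list or numeric vector with unit-cell lengths \code{a}, \code{b},
#'   \code{c} in angstroms and angles \code{alpha}, \code{beta}, \code{gamma}
#'   in degrees.
#' @return 3x3 numeric matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  cell <- as_cell(cell)
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

as_cell <- function(cell) {
  if (is.numeric(cell) && length(cell) == 6) {
    cell <- as.list(cell)
    names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  }
  stopifnot(is.list(cell),
            all(c("a", "b", "c", "alpha", "beta", "gamma") %in% names(cell)))
  for (k in c("a", "b", "c"))
    if (cell[[k]] <= 0) stop("unit-cell length ", k, " must be positive")
  for (k in c("alpha", "beta", "gamma"))
    if (cell[[k]] <= 0 || cell[[k]] >= 180)
      stop("unit-cell angle ", k, " must be in (0, 180) degrees")
  cell[c("a", "b", "c", "alpha", "beta", "gamma")]
}

cell_volume <- function(cell) {
  m <- orthogonalization_matrix(cell)
  abs(det(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
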