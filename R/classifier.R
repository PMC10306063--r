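# Reference density-shell residue-type classifier.
#
# The classifier contract is deliberately pluggable: any function
# (model, map, residue) -> valid 20-class probability row can replace the
# baseline. The baseline compares radial shell-mean densities around the
# side-chain anchor (CB, or an ideal pseudo-CB for glycine) with the expected
# side-chain heavy-atom occupancy of each residue type.

# Ideal side-chain heavy-atom distances (A) from CB, including CB itself at 0.
# Totals match standard heavy-atom counts (GLY 0 ... TRP 10).
SIDECHAIN_DIST <- list(
  G = numeric(0),
  A = 0,
  S = c(0, 1.42),
  C = c(0, 1.81),
  T = c(0, 1.43, 1.52),
  V = c(0, 1.52, 1.52),
  P = c(0, 1.50, 2.39),
  N = c(0, 1.52, 2.41, 2.47),
  D = c(0, 1.52, 2.41, 2.47),
  I = c(0, 1.53, 1.53, 2.56),
  L = c(0, 1.53, 2.54, 2.54),
  M = c(0, 1.52, 2.81, 4.24),
  E = c(0, 1.52, 2.56, 3.62, 3.70),
  Q = c(0, 1.52, 2.56, 3.62, 3.70),
  K = c(0, 1.52, 2.56, 3.93, 5.06),
  H = c(0, 1.50, 2.72, 2.74, 3.96, 3.99),
  R = c(0, 1.52, 2.56, 3.93, 5.02, 6.10, 5.90),
  F = c(0, 1.50, 2.58, 2.58, 3.90, 3.90, 4.40),
  Y = c(0, 1.50, 2.58, 2.58, 3.90, 3.90, 4.40, 5.76),
  W = c(0, 1.50, 2.53, 2.55, 3.69, 3.73, 3.88, 4.95, 5.12, 5.92))

#' Configuration of the density-shell baseline classifier
#'
#' @param shell_edges strictly increasing radial shell boundaries in angstroms
#'   around the side-chain anchor.
#' @param samples_per_shell number of deterministic sample points per shell.
#' @param softmax_temperature temperature applied to the template-match score.
#' @param probability_floor small mass added to every class before
#'   renormalization; must lie in (0, 1/20).
#' @param blur_sigma Gaussian width (angstroms) assumed for the atomic
#'   density when building the expected shell-density templates; roughly
#'   map resolution / 2.4.
#' @return a \code{classifier_config} list.
#' @export
classifier_config <- function(shell_edges = c(0, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5),
                              samples_per_shell = 64L,
                              softmax_temperature = 2,
                              probability_floor = 1e-4,
                              blur_sigma = 1.0) {
  stopifnot(all(diff(shell_edges) > 0), samples_per_shell >= 1,
            softmax_temperature > 0,
            probability_floor > 0, probability_floor < 1 / 20,
            blur_sigma > 0)
  structure(list(shell_edges = shell_edges,
                 samples_per_shell = as.integer(samples_per_shell),
                 softmax_temperature = softmax_temperature,
                 probability_floor = probability_floor,
                 blur_sigma = blur_sigma),
            class = "classifier_config")
}

# Backbone heavy-atom distances from CB (own N/CA/C/O plus the flanking
# peptide units); a type-independent additive term of every template.
BACKBONE_DIST <- c(1.53, 2.45, 2.50, 3.30, 4.40, 4.60)

# Mean over the spherical shell [r0, r1] of a unit Gaussian of width sigma
# centered at distance d from the shell center (exact radial form, numeric
# quadrature over r).
shell_mean_gaussian <- function(r0, r1, d, sigma) {
  f <- function(r) {
    a <- exp(-(r - d)^2 / (2 * sigma^2)) - exp(-(r + d)^2 / (2 * sigma^2))
    ifelse(r * d > 1e-12, sigma^2 * a / (r * d),
           exp(-(r^2 + d^2) / (2 * sigma^2)) * 2)  # limit d -> 0 or r -> 0
  }
  r <- seq(r0, r1, length.out = 33)
  w <- 4 * pi * r^2 * f(r)
  vol <- 4 / 3 * pi * (r1^3 - r0^3)
  # Simpson weights
  sw <- c(1, rep(c(4, 2), 16))[1:33]; sw[33] <- 1
  sum(sw * w) * (r1 - r0) / 32 / 3 / vol
}

# Expected shell-mean density mu[type, shell]: every side-chain heavy atom
# at its ideal distance from CB, plus the common backbone atoms, smeared by
# the blur width and averaged over each shell. The result is cached per
# configuration (edges + blur).
occupancy_table <- function(config) {
  key <- paste0("mu_", paste(signif(c(config$shell_edges,
                                      config$blur_sigma), 10),
                             collapse = "_"))
  hit <- get0(key, envir = .template_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  edges <- config$shell_edges
  k <- length(edges) - 1
  mu <- matrix(0, nrow = 20, ncol = k, dimnames = list(AA1, NULL))
  for (a in AA1) {
    dists <- c(SIDECHAIN_DIST[[a]], BACKBONE_DIST)
    for (s in seq_len(k))
      mu[a, s] <- sum(vapply(dists, function(d)
        shell_mean_gaussian(edges[s], edges[s + 1], d, config$blur_sigma),
        numeric(1)))
  }
  assign(key, mu, envir = .template_cache)
  mu
}

.template_cache <- new.env(parent = emptyenv())

# Deterministic quasi-uniform points on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Sample points filling shell (r0, r1] quasi-uniformly by volume.
shell_points <- function(r0, r1, n) {
  dirs <- fibonacci_sphere(n)
  j <- seq_len(n) - 0.5
  radius <- (r0^3 + j / n * (r1^3 - r0^3))^(1 / 3)
  dirs * radius
}

# Ideal CB position from backbone N, CA, C (standard tetrahedral construction).
pseudo_cb <- function(n, ca, c) {
  b1 <- ca - n
  b2 <- c - ca
  cr <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  ca + (-0.58273431 * cr + 0.56802827 * b1 - 0.54067466 * b2)
}

residue_anchor <- function(residue) {
  at <- residue$atoms
  if ("CB" %in% rownames(at)) return(at["CB", ])
  need <- c("N", "CA", "C")
  if (!all(need %in% rownames(at))) return(NULL)
  pseudo_cb(at["N", ], at["CA", ], at["C", ])
}

#' Radial shell-density features of one residue
#'
#' Feature k is the mean interpolated density over deterministic sample
#' points in shell k around the side-chain anchor, minus the mean density at
#' the residue's backbone atoms (a local baseline). Sample points within 3
#' angstroms of an atom from another chain are masked out.
#'
#' @param residue a residue from a \code{structure_model} chain; must carry
#'   N, CA and C (CB is used as anchor when present).
#' @param map a \code{density_map}.
#' @param config a \code{classifier_config}.
#' @param mask_atoms optional m x 3 matrix of atom positions from other
#'   chains used for contact masking.
#' @return numeric feature vector, one mean density per shell.
#' @export
shell_features <- function(residue, map, config = classifier_config(),
                           mask_atoms = NULL) {
  anchor <- residue_anchor(residue)
  if (is.null(anchor))
    stop("residue ", residue$number, " lacks N/CA/C backbone atoms")
  at <- residue$atoms
  bb <- at[rownames(at) %in% c("N", "CA", "C", "O"), , drop = FALSE]
  baseline <- mean(interpolate_map(map, bb))
  edges <- config$shell_edges
  k <- length(edges) - 1
  feats <- numeric(k)
  for (s in seq_len(k)) {
    pts <- sweep(shell_points(edges[s], edges[s + 1],
                              config$samples_per_shell), 2, anchor, `+`)
    if (!is.null(mask_atoms) && nrow(mask_atoms) > 0) {
      d2min <- apply(pts, 1, function(p)
        min(colSums((t(mask_atoms) - p)^2)))
      pts <- pts[d2min >= 9, , drop = FALSE]  # 3 A contact mask
    }
    feats[s] <- if (nrow(pts) == 0) 0 else
      mean(interpolate_map(map, pts)) - baseline
  }
  feats
}

#' Classify a residue's shell features into 20-class probabilities
#'
#' The score of type \code{a} is the negative squared residual between the
#' observed shell features and the type's expected shell occupancy, after
#' fitting a per-type least-squares scale (non-negative) and intercept; the
#' intercept absorbs the local baseline level, making the score invariant to
#' constant offsets of the features. Probabilities are a tempered softmax of
#' the scores, floored and renormalized.
#'
#' @param features numeric shell-feature vector.
#' @param config a \code{classifier_config}.
#' @return named numeric vector of 20 probabilities (order \code{A..Y},
#'   alphabetical one-letter), summing to 1.
#' @export
classify_residue <- function(features, config = classifier_config()) {
  stopifnot(all(is.finite(features)))
  mu <- occupancy_table(config)
  if (length(features) != ncol(mu))
    stop("feature length ", length(features), " != number of shells ", ncol(mu))
  k <- length(features)
  scores <- vapply(AA1, function(a) {
    m <- mu[a, ]
    vm <- sum((m - mean(m))^2)
    s <- if (vm > 0)
      max(0, sum((features - mean(features)) * (m - mean(m))) / vm) else 0
    b <- mean(features) - s * mean(m)
    -sum((features - s * m - b)^2)
  }, numeric(1))
  z <- scores / config$softmax_temperature
  p <- exp(z - max(z))
  p <- p / sum(p)
  p <- (p + config$probability_floor) / (1 + 20 * config$probability_floor)
  stats::setNames(p, AA1)
}

#' Per-residue probability profile of a chain from model and map
#'
#' @param model a \code{structure_model}.
#' @param map a \code{density_map}.
#' @param chain_id chain to profile.
#' @param classifier either \code{NULL} (density-shell baseline) or a function
#'   \code{(model, map, residue) -> 20 probabilities} in \code{A..Y} order.
#' @param config a \code{classifier_config} for the baseline.
#' @return a \code{residue_profile}; rows of residues that could not be
#'   classified (missing backbone) are uniform and flagged.
#' @export
extract_profile <- function(model, map, chain_id, classifier = NULL,
                            config = classifier_config()) {
  chain <- chain_from_model(model, chain_id)
  n <- length(chain$residues)
  probs <- matrix(1 / 20, nrow = n, ncol = 20, dimnames = list(NULL, AA1))
  flagged <- logical(n)
  mask_atoms <- other_chain_atoms(model, chain_id)
  for (i in seq_len(n)) {
    r <- chain$residues[[i]]
    row <- tryCatch({
      if (is.null(classifier))
        classify_residue(shell_features(r, map, config, mask_atoms), config)
      else classifier(model, map, r)
    }, error = function(e) NULL)
    if (is.null(row)) {
      flagged[i] <- TRUE
    } else {
      row <- as.numeric(row)
      if (length(row) != 20 || any(row < 0) || abs(sum(row) - 1) > 1e-6)
        stop("classifier returned an invalid probability row for residue ",
             r$number)
      probs[i, ] <- row / sum(row)
    }
  }
  residue_profile(chain_id,
                  number = vapply(chain$residues, `[[`, integer(1), "number"),
                  icode = vapply(chain$residues, `[[`, character(1), "icode"),
                  probs = probs, flagged = flagged)
}

other_chain_atoms <- function(model, chain_id) {
  out <- list()
  for (ch in model$chains) {
    if (ch$id == chain_id) next
    for (r in ch$residues) out[[length(out) + 1L]] <- r$atoms
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}
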