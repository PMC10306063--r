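# Gapless profile-to-sequence alignment with calibrated p-values.
#
# A window of per-residue class probabilities is scored against a target
# sequence at a given offset as the summed per-position log-odds against a
# background composition. The null distribution of that score under an
# i.i.d. background sequence is computed exactly by convolving per-position
# score distributions on a lattice; the tail probability is corrected for
# the number of candidate offsets with an independence (extreme-value)
# correction 1 - (1 - tail)^M.

#' Alignment scoring parameters
#'
#' @param background amino-acid background frequencies, length 20 in
#'   \code{A..Y} order (default uniform 1/20).
#' @param grid_step lattice step of the null-score discretization, in nats.
#' @param pvalue_threshold decision threshold on the alignment p-value; 0.14
#'   is the calibrated operating point for register-error detection.
#' @param probability_floor mass added to profile rows before taking logs
#'   (numerical guard against zero probabilities).
#' @param trunc_tail cumulative tail mass trimmed per convolution step.
#' @return an \code{alignment_params} list.
#' @export
alignment_params <- function(background = rep(1 / 20, 20),
                             grid_step = 0.01,
                             pvalue_threshold = 0.14,
                             probability_floor = 1e-4,
                             trunc_tail = 1e-12) {
  stopifnot(length(background) == 20, all(background > 0),
            abs(sum(background) - 1) < 1e-9,
            grid_step > 0, pvalue_threshold > 0, pvalue_threshold < 1,
            probability_floor > 0, probability_floor < 1 / 20)
  structure(list(background = background / sum(background),
                 grid_step = grid_step,
                 pvalue_threshold = pvalue_threshold,
                 probability_floor = probability_floor,
                 trunc_tail = trunc_tail),
            class = "alignment_params")
}

# Floor and renormalize profile rows; returns an L x 20 matrix.
floor_rows <- function(window, floor_value) {
  window <- as.matrix(window)
  if (ncol(window) != 20) stop("profile window must have 20 columns")
  w <- sweep(window, 1, rowSums(window), `/`)
  (w + floor_value) / (1 + 20 * floor_value)
}

seq_to_index <- function(residues) {
  letters <- strsplit(residues, "")[[1]]
  idx <- match(letters, AA1)
  idx[letters == "X"] <- 21L  # scored as zero contribution
  if (any(is.na(idx)))
    stop("sequence contains an illegal letter '",
         letters[which(is.na(idx))[1]], "'")
  idx
}

# log-odds matrix with a 21st zero column for 'X' positions
log_odds <- function(window, params) {
  w <- floor_rows(window, params$probability_floor)
  lr <- sweep(log(w), 2, log(params$background), `-`)
  cbind(lr, 0)
}

#' Score a gapless alignment of a profile window against a sequence
#'
#' The score is \eqn{\sum_i \log(P_i(a_{o+i}) / q(a_{o+i}))} in nats, with
#' floored, renormalized profile rows; an \code{X} in the sequence contributes
#' zero.
#'
#' @param window L x 20 matrix of per-residue class probabilities
#'   (\code{A..Y} order).
#' @param seq a \code{target_sequence}.
#' @param offset 0-based start position of the window in the sequence.
#' @param params an \code{alignment_params}.
#' @return alignment score in nats.
#' @export
alignment_score <- function(window, seq, offset, params = alignment_params()) {
  l <- nrow(as.matrix(window))
  n <- nchar(seq$residues)
  if (offset < 0 || offset > n - l)
    stop("offset ", offset, " out of range for window length ", l,
         " in sequence of length ", n)
  lr <- log_odds(window, params)
  idx <- seq_to_index(seq$residues)[offset + seq_len(l)]
  sum(lr[cbind(seq_len(l), idx)])
}

# Scores of a window at every valid offset of one sequence (vectorized).
all_offset_scores <- function(lr, seq_idx, l) {
  n <- length(seq_idx)
  if (n < l) return(numeric(0))
  pos <- outer(seq_len(l), 0:(n - l), `+`)   # residue position per (i, offset)
  val <- lr[cbind(rep(seq_len(l), ncol(pos)), seq_idx[as.vector(pos)])]
  colSums(matrix(val, nrow = l))
}

#' Best gapless alignment of a window over a set of target sequences
#'
#' All valid offsets of all sequences are scanned; ties are broken by
#' sequence order, then lowest offset.
#'
#' @param window L x 20 probability matrix.
#' @param sequences list of \code{target_sequence} objects.
#' @param params an \code{alignment_params}.
#' @return list with \code{seq_id}, \code{offset} (0-based), \code{score}
#'   (nats) and \code{n_offsets} (total number of candidate offsets M).
#' @export
best_gapless_alignment <- function(window, sequences,
                                   params = alignment_params()) {
  window <- as.matrix(window)
  l <- nrow(window)
  lr <- log_odds(window, params)
  best <- NULL
  m_total <- 0L
  for (s in sequences) {
    idx <- seq_to_index(s$residues)
    sc <- all_offset_scores(lr, idx, l)
    m_total <- m_total + length(sc)
    if (length(sc) == 0) next
    o <- which.max(sc)  # first maximum = lowest offset
    if (is.null(best) || sc[o] > best$score)
      best <- list(seq_id = s$id, offset = o - 1L, score = sc[o])
  }
  if (is.null(best))
    stop("no target sequence is long enough for a window of length ", l)
  best$n_offsets <- m_total
  best
}

#' Null distribution of the single-offset alignment score
#'
#' Under the null, the aligned sequence is i.i.d. from the background; at
#' each window position the score takes value \eqn{\log(P_i(a)/q(a))} with
#' probability \eqn{q(a)}. Atom values are binned onto a lattice of
#' \code{grid_step} nats (rounding down) and positions are convolved exactly.
#' Identical windows (up to per-row reordering of atom values) share a cached
#' result.
#'
#' @param window L x 20 probability matrix.
#' @param params an \code{alignment_params}.
#' @return object of class \code{score_null}: lattice \code{step}, integer
#'   \code{offset} of the first bin, \code{mass} vector, window length
#'   \code{l}.
#' @export
null_score_distribution <- function(window, params = alignment_params()) {
  window <- as.matrix(window)
  lr <- log_odds(window, params)[, 1:20, drop = FALSE]
  bins <- matrix(as.integer(floor(lr / params$grid_step + 1e-9)),
                 nrow = nrow(window))
  null_distribution_from_bins(bins, params)
}

# cache-aware convolution from pre-binned atoms (hot path of the scanner)
null_distribution_from_bins <- function(bins, params) {
  l <- nrow(bins)
  key <- null_cache_key(bins, params)
  hit <- get0(key, envir = .null_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- cpp_null_convolve(bins, params$background, params$trunc_tail)
  out <- structure(list(step = params$grid_step, offset = res$offset,
                        mass = res$mass,
                        tail_from = rev(cumsum(rev(res$mass))), l = l),
                   class = "score_null")
  if (length(ls(.null_cache)) > 512) rm(list = ls(.null_cache),
                                        envir = .null_cache)
  assign(key, out, envir = .null_cache)
  out
}

.null_cache <- new.env(parent = emptyenv())

# Cache key: the multiset of (bin, background) atoms per position, with
# position order ignored - the convolution is invariant to both.
null_cache_key <- function(bins, params) {
  qsig <- paste(signif(params$background, 12), collapse = ",")
  paste0("k", cpp_bins_key(bins), "_", nrow(bins), "_",
         sum(utf8ToInt(qsig) * seq_len(nchar(qsig))) %% 1e9)
}

#' Tail probability of the null score distribution
#'
#' @param null a \code{score_null}.
#' @param score observed score in nats.
#' @return \eqn{P(S \ge score)} under the null. The lookup threshold is
#'   lowered by \code{l - 1} lattice bins so that the discretized tail is
#'   provably at least the exact tail (per-position floors can lose at most
#'   one bin each).
#' @export
null_tail <- function(null, score) {
  kthr <- floor(score / null$step + 1e-9) - (null$l - 1L)
  i <- kthr - null$offset + 1
  n <- length(null$mass)
  if (i <= 1) return(1)
  if (i > n) return(0)
  null$tail_from[i]
}

#' Alignment p-value with multiple-offset correction
#'
#' @param score observed alignment score in nats.
#' @param null a \code{score_null} for the same window.
#' @param n_offsets number of candidate offsets M scanned for the best
#'   alignment.
#' @return p-value \eqn{1 - (1 - tail)^M}, clamped into (0, 1]; the
#'   probability that an equally good alignment arises by chance among M
#'   random placements.
#' @export
alignment_pvalue <- function(score, null, n_offsets) {
  stopifnot(n_offsets >= 1)
  tail <- null_tail(null, score)
  p <- 1 - (1 - tail)^n_offsets
  if (tail > 0 && p == 0) p <- n_offsets * tail  # underflow guard
  min(max(p, 1e-300), 1)
}

# All sliding-window scores of a segment against a target at every offset.
# scores[w, o+1] = sum_{t=0..l-1} lr[w+t, seq[o+t]] computed by a reverse
# cumulative sum along the diagonals of the position-by-target score matrix.
segment_window_scores <- function(lr, seq_idx, l) {
  n <- nrow(lr)
  nt <- length(seq_idx)
  cmat <- matrix(lr[cbind(rep(seq_len(n), nt),
                          rep(seq_idx, each = n))], nrow = n)
  d <- matrix(0, n + 1L, nt + 1L)
  for (i in n:1)
    d[i, 1:nt] <- cmat[i, ] + d[i + 1L, 2:(nt + 1L)]
  nw <- n - l + 1L
  noff <- nt - l + 1L
  scores <- d[1:nw, 1:noff, drop = FALSE] -
    d[(1L + l):(nw + l), (1L + l):(noff + l), drop = FALSE]
  list(scores = scores)
}

#' Best alignment of a window with its p-value
#'
#' Convenience wrapper: best gapless alignment, null distribution and
#' offset-corrected p-value in one call.
#'
#' @inheritParams best_gapless_alignment
#' @return list with \code{seq_id}, \code{offset}, \code{score},
#'   \code{n_offsets} and \code{pvalue}.
#' @export
window_alignment <- function(window, sequences, params = alignment_params()) {
  best <- best_gapless_alignment(window, sequences, params)
  null <- null_score_distribution(window, params)
  best$pvalue <- alignment_pvalue(best$score, null, best$n_offsets)
  best
}
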