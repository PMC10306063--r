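# Synthetic ground-truth benchmarks.
#
# The generator emulates the statistical output of a residue-type classifier
# (per-residue 20-class posteriors with a tunable accuracy), injects register
# shifts, numbering gaps and point mismatches with known ground truth, and
# scores detector output against that truth. It produces profiles directly;
# density-level simulation lives with the classifier (simulate_map).

#' Specification of a synthetic benchmark chain
#'
#' @param chain_length number of modelled residues.
#' @param accuracy classifier accuracy alpha in (0, 1]: probability that a
#'   residue's predicted type equals its true type.
#' @param confusion \code{"uniform"} or \code{"similarity"} (extra confusion
#'   mass within the look-alike groups D/N, E/Q, V/T/I, F/Y).
#' @param shifts list of \code{c(start, end, offset)} register-shift regions
#'   in model positions (1-based, non-overlapping): the residue at model
#'   position i truly represents target position i + offset while the model
#'   claims i.
#' @param numbering_gaps list of \code{c(position, gap)}: author numbering
#'   jumps by \code{gap} after \code{position} (identities unchanged).
#' @param mismatches list of \code{c(position, type)}: the claimed residue
#'   type at \code{position} is replaced by \code{type} (one letter, possibly
#'   \code{"X"}).
#' @param jitter lognormal row jitter of the generated profile (0 = none).
#' @param seed integer seed driving all randomness.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(chain_length = 300L, accuracy = 0.9,
                           confusion = c("uniform", "similarity"),
                           shifts = list(), numbering_gaps = list(),
                           mismatches = list(), jitter = 0, seed = 1L) {
  confusion <- match.arg(confusion)
  stopifnot(chain_length >= 1, accuracy > 0, accuracy <= 1, jitter >= 0)
  for (s in shifts) {
    stopifnot(length(s) == 3, s[1] >= 1, s[2] <= chain_length, s[1] <= s[2],
              s[3] != 0)
  }
  if (length(shifts) > 1) {
    spans <- do.call(rbind, lapply(shifts, function(s) s[1:2]))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2]))
      stop("shift regions must not overlap")
  }
  structure(list(chain_length = as.integer(chain_length), accuracy = accuracy,
                 confusion = confusion, shifts = shifts,
                 numbering_gaps = numbering_gaps, mismatches = mismatches,
                 jitter = jitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random target sequence
#'
#' @param length sequence length (> 0).
#' @param background amino-acid sampling frequencies in \code{A..Y} order.
#' @param seed integer seed; the draw is deterministic given it.
#' @param id sequence identifier.
#' @return a \code{target_sequence}.
#' @export
gen_sequence <- function(length, background = rep(1 / 20, 20), seed = 1L,
                         id = "target") {
  if (length < 1) stop("sequence length must be positive")
  stopifnot(length(background) == 20, all(background >= 0))
  letters <- with_seed(seed,
    sample(AA1, length, replace = TRUE, prob = background))
  target_sequence(id, paste(letters, collapse = ""))
}

confusion_kernel <- function(confusion) {
  k <- matrix(1, 20, 20, dimnames = list(AA1, AA1))
  if (confusion == "similarity") {
    for (grp in list(c("D", "N"), c("E", "Q"), c("V", "T", "I"),
                     c("F", "Y")))
      k[grp, grp] <- 4
  }
  diag(k) <- 0
  sweep(k, 1, rowSums(k), `/`)
}

#' Inject model errors into a claimed assignment
#'
#' Builds the claimed chain (types follow the target at the claimed
#' positions) and the ground truth (the target position each residue's
#' density actually represents). Register shifts change only the truth;
#' numbering gaps change only the author numbers; mismatches change only the
#' claimed types.
#'
#' @param spec a \code{synthetic_spec}.
#' @param target a \code{target_sequence}; positions are 1-based throughout.
#' @param chain_id chain identifier for the generated chain.
#' @return list with \code{chain} (claimed model chain, no coordinates) and
#'   \code{truth} (a \code{ground_truth}: per-residue true target positions,
#'   author numbers and the injected region list).
#' @export
inject_errors <- function(spec, target, chain_id = "A") {
  n <- spec$chain_length
  tl <- strsplit(target$residues, "")[[1]]
  claimed_pos <- seq_len(n)
  true_pos <- seq_len(n)
  for (s in spec$shifts)
    true_pos[s[1]:s[2]] <- claimed_pos[s[1]:s[2]] + s[3]
  if (any(true_pos < 1 | true_pos > length(tl)))
    stop("a shift region maps outside the target sequence")
  numbers <- seq_len(n)
  for (g in spec$numbering_gaps) {
    p <- g[1]
    if (p < n) numbers[(p + 1L):n] <- numbers[(p + 1L):n] + g[2]
  }
  claimed_type <- tl[claimed_pos]
  for (m in spec$mismatches) {
    p <- as.integer(m[1])
    claimed_type[p] <- toupper(m[2])
  }
  residues <- lapply(seq_len(n), function(i)
    new_residue(numbers[i], "", aa_one_to_three(claimed_type[i]),
                matrix(numeric(0), ncol = 3)))
  chain <- new_chain(chain_id, residues)
  regions <- lapply(spec$shifts, function(s)
    data.frame(chain = chain_id, category = "register_shift",
               start = numbers[s[1]], end = numbers[s[2]],
               offset = as.integer(s[3]), stringsAsFactors = FALSE))
  regions <- c(regions, lapply(spec$mismatches, function(m)
    data.frame(chain = chain_id, category = "sequence_mismatch",
               start = numbers[as.integer(m[1])],
               end = numbers[as.integer(m[1])],
               offset = NA_integer_, stringsAsFactors = FALSE)))
  regions <- if (length(regions)) do.call(rbind, regions) else
    empty_regions()[, c("chain", "category", "start", "end", "offset")]
  truth <- structure(list(true_pos = as.integer(true_pos),
                          numbers = as.integer(numbers),
                          target_id = target$id, regions = regions),
                     class = "ground_truth")
  list(chain = chain, truth = truth)
}

#' Generate a classifier-like probability profile from ground truth
#'
#' For each residue a predicted type is drawn: the true type (the one implied
#' by the density, i.e. the ground truth) with probability \code{alpha},
#' otherwise a confusion draw among the remaining 19. The row then places
#' mass \code{alpha} on the predicted type and spreads \code{1 - alpha} by
#' the confusion kernel, with optional lognormal jitter.
#'
#' @param target the \code{target_sequence} the truth refers to.
#' @param truth a \code{ground_truth} from [inject_errors()].
#' @param alpha classifier accuracy in (0, 1].
#' @param confusion \code{"uniform"} or \code{"similarity"}.
#' @param jitter lognormal sd of per-entry row jitter (0 = none).
#' @param seed integer seed.
#' @param chain_id chain the profile describes.
#' @return a \code{residue_profile}.
#' @export
gen_profile <- function(target, truth, alpha, confusion = "uniform",
                        jitter = 0, seed = 1L, chain_id = "A") {
  stopifnot(alpha > 0, alpha <= 1)
  tl <- strsplit(target$residues, "")[[1]]
  true_type <- tl[truth$true_pos]
  n <- length(true_type)
  kern <- confusion_kernel(confusion)
  probs <- with_seed(seed, {
    p <- matrix(0, n, 20, dimnames = list(NULL, AA1))
    correct <- stats::runif(n) < alpha
    for (i in seq_len(n)) {
      tt <- true_type[i]
      if (!tt %in% AA1) { p[i, ] <- 1 / 20; next }  # unknown true type
      pred <- if (correct[i] || alpha == 1) tt else
        sample(AA1, 1, prob = kern[tt, ])
      row <- (1 - alpha) * kern[pred, ]
      row[pred] <- row[pred] + alpha
      if (jitter > 0) {
        row <- row * exp(stats::rnorm(20, sd = jitter))
        row <- row / sum(row)
      }
      p[i, ] <- row
    }
    p
  })
  residue_profile(chain_id, number = truth$numbers, probs = probs)
}

#' Convenience generator: one synthetic benchmark chain
#'
#' Draws a target sequence, injects the specified errors and generates the
#' matching profile, all from one seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @param target optional pre-drawn \code{target_sequence}; drawn from the
#'   spec's seed when absent.
#' @param chain_id chain identifier.
#' @return list with \code{target}, \code{chain}, \code{truth} and
#'   \code{profile}.
#' @export
make_benchmark <- function(spec, target = NULL, chain_id = "A") {
  if (is.null(target))
    target <- gen_sequence(spec$chain_length + max_shift(spec),
                           seed = spec$seed * 7L + 1L)
  inj <- inject_errors(spec, target, chain_id)
  profile <- gen_profile(target, inj$truth, spec$accuracy, spec$confusion,
                         spec$jitter, seed = spec$seed * 7L + 2L,
                         chain_id = chain_id)
  list(target = target, chain = inj$chain, truth = inj$truth,
       profile = profile)
}

max_shift <- function(spec) {
  if (length(spec$shifts) == 0) return(0L)
  max(0L, vapply(spec$shifts, function(s) as.integer(s[3]), integer(1)))
}

#' Randomly sample continuous test fragments from a model
#'
#' Per chain and per fragment length, up to \code{n_per_length} start
#' positions are drawn uniformly without replacement. Fragments containing
#' unknown (\code{X}) residues are rejected, as are fragments whose residue
#' count does not match the difference between flanking residue numbers or
#' that carry insertion codes (possibly non-continuous); rejection may leave
#' fewer fragments than requested.
#'
#' @param model a \code{structure_model}.
#' @param lengths fragment lengths to sample (default 10 and 20 residues).
#' @param n_per_length fragments drawn per chain and length (default 3).
#' @param seed integer seed.
#' @return list of fragments: \code{chain_id}, \code{length}, \code{start}
#'   (chain index), \code{numbers}, \code{sequence}.
#' @export
sample_fragments <- function(model, lengths = c(10L, 20L), n_per_length = 3L,
                             seed = 1L) {
  lengths <- as.integer(lengths)
  frags <- list()
  with_seed(seed, {
    for (ch in model$chains) {
      ms <- model_sequence(ch)
      letters <- strsplit(ms$sequence, "")[[1]]
      ico <- vapply(ch$residues, `[[`, character(1), "icode")
      n <- length(letters)
      for (l in lengths) {
        if (n < l) next
        starts <- seq_len(n - l + 1L)
        draw <- if (length(starts) <= n_per_length) starts else
          sample(starts, n_per_length)
        for (s in sort(draw)) {
          idx <- s:(s + l - 1L)
          if (any(letters[idx] == "X")) next          # UNK rejection
          if (any(ico[idx] != "")) next               # insertion codes
          if (ms$numbers[idx[l]] - ms$numbers[idx[1]] + 1L != l) next
          frags[[length(frags) + 1L]] <- list(
            chain_id = ch$id, length = l, start = s,
            numbers = ms$numbers[idx],
            sequence = paste(letters[idx], collapse = ""))
        }
      }
    }
  })
  frags
}

#' Score detected issue regions against ground truth
#'
#' A detected region matches a true region when the categories agree, the
#' offsets agree (both absent counts as agreement) and the spans overlap by
#' at least half of the true span. Boundary error of a matched pair is the
#' larger of the two endpoint discrepancies.
#'
#' @param detected data frame of issue regions (as from [categorize_calls()]).
#' @param truth a \code{ground_truth}, or a data frame of true regions.
#' @return list with \code{recall}, \code{precision}, \code{n_true},
#'   \code{n_detected}, per-match \code{boundary_errors}, and their median
#'   and 90th percentile.
#' @export
evaluate_regions <- function(detected, truth) {
  tr <- if (inherits(truth, "ground_truth")) truth$regions else truth
  nd <- nrow(detected); nt <- nrow(tr)
  matched_d <- logical(nd)
  errors <- numeric(0)
  matched_t <- 0L
  for (i in seq_len(nt)) {
    span_t <- tr$end[i] - tr$start[i] + 1L
    best_j <- 0L; best_ov <- 0L
    for (j in seq_len(nd)) {
      if (matched_d[j]) next
      if (detected$category[j] != tr$category[i]) next
      off_ok <- (is.na(detected$offset[j]) && is.na(tr$offset[i])) ||
        (!is.na(detected$offset[j]) && !is.na(tr$offset[i]) &&
           detected$offset[j] == tr$offset[i])
      if (!off_ok) next
      ov <- min(detected$end[j], tr$end[i]) -
        max(detected$start[j], tr$start[i]) + 1L
      if (ov >= span_t / 2 && ov > best_ov) { best_ov <- ov; best_j <- j }
    }
    if (best_j > 0L) {
      matched_d[best_j] <- TRUE
      matched_t <- matched_t + 1L
      errors <- c(errors, max(abs(detected$start[best_j] - tr$start[i]),
                              abs(detected$end[best_j] - tr$end[i])))
    }
  }
  list(recall = if (nt) matched_t / nt else NA_real_,
       precision = if (nd) sum(matched_d) / nd else NA_real_,
       n_true = nt, n_detected = nd, boundary_errors = errors,
       median_boundary_error = if (length(errors))
         stats::median(errors) else NA_real_,
       p90_boundary_error = if (length(errors))
         unname(stats::quantile(errors, 0.9, type = 1)) else NA_real_)
}

#' Generate a synthetic protein structure with coordinates
#'
#' An extended-conformation chain in a P1 orthogonal cell: backbone atoms
#' along x, side-chain heavy atoms placed at their ideal distances from CB in
#' alternating directions. Geometry is schematic (synthetic) - adequate for
#' exercising density simulation and the shell classifier, not for
#' stereochemistry.
#'
#' @param sequence one-letter sequence of the chain (or an integer length,
#'   in which case a random sequence is drawn from \code{seed}).
#' @param seed integer seed used when \code{sequence} is a length.
#' @param chain_id chain identifier.
#' @return a \code{structure_model} with one chain.
#' @export
gen_structure <- function(sequence, seed = 1L, chain_id = "A") {
  if (is.numeric(sequence))
    sequence <- gen_sequence(as.integer(sequence), seed = seed)$residues
  letters <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters)
  margin <- 14
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    x <- margin + 3.3 * (i - 1)
    up <- if (i %% 2 == 0) 1 else -1
    ca <- c(x, margin + 0.9 * up, margin)
    nn <- ca + c(-1.2, -0.8 * up, 0)
    cc <- ca + c(1.25, -0.8 * up, 0)
    oo <- cc + c(0.2, -1.2 * up, 0)
    at <- rbind(N = nn, CA = ca, C = cc, O = oo)
    d <- SIDECHAIN_DIST[[letters[i]]]
    if (is.null(d)) d <- numeric(0)  # 'X': no side chain
    if (length(d) > 0) {
      u0 <- c(0, 0.35 * up, 0.94)
      u0 <- u0 / sqrt(sum(u0^2))
      cb <- ca + 1.53 * u0
      at <- rbind(at, CB = cb)
      extra <- d[-1]
      if (length(extra) > 0) {
        for (k in seq_along(extra)) {
          # deterministic fan of directions around the outward axis
          ang <- 0.45 * sin(2.399 * k)
          dir <- u0 + c(0.35 * sin(ang + k), 0.15 * cos(1.7 * k), 0.35 *
                          cos(ang))
          dir <- dir / sqrt(sum(dir^2))
          at <- rbind(at, dir * extra[k] + cb)
          rownames(at)[nrow(at)] <- paste0("S", k)
        }
      }
    }
    type3 <- aa_one_to_three(letters[i])
    residues[[i]] <- new_residue(i, "", type3, at)
  }
  cell <- c(2 * margin + 3.3 * n, 2 * margin, 2 * margin, 90, 90, 90)
  new_structure_model(stats::setNames(list(new_chain(chain_id, residues)),
                                      chain_id), cell)
}
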