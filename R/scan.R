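# Sliding-window register scanning and issue categorization.
#
# Each continuous residue-numbering segment of a chain is scanned with
# overlapping profile windows. Every window is re-aligned against the
# assigned target sequence; windows whose best alignment is both confident
# (p-value below threshold) and different from the model's claimed register
# are merged into issue regions.

#' Scanner configuration
#'
#' @param window_length residues per scan window (default 20; 10 is the
#'   short-fragment alternative).
#' @param step window stride in residues.
#' @param pvalue_threshold alignment p-value below which a window verdict is
#'   considered confident (default 0.14).
#' @param min_chain_length shortest chain/segment for which assignment is
#'   attempted (default 10).
#' @param merge_gap maximum separation in residues between same-offset
#'   shifted windows merged into one region.
#' @param max_assign_length cap on the segment length used for whole-chain
#'   sequence assignment (the p-value saturates long before this).
#' @param align an \code{alignment_params}; its threshold is kept in sync
#'   with \code{pvalue_threshold}.
#' @return a \code{scan_config} list.
#' @export
scan_config <- function(window_length = 20L, step = 1L,
                        pvalue_threshold = 0.14, min_chain_length = 10L,
                        merge_gap = 5L, max_assign_length = 100L,
                        align = alignment_params(pvalue_threshold =
                                                   pvalue_threshold)) {
  stopifnot(window_length >= 5, step >= 1, min_chain_length >= 1,
            merge_gap >= 0, max_assign_length >= 10)
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step),
                 pvalue_threshold = pvalue_threshold,
                 min_chain_length = as.integer(min_chain_length),
                 merge_gap = as.integer(merge_gap),
                 max_assign_length = as.integer(max_assign_length),
                 align = align),
            class = "scan_config")
}

# Continuous residue-numbering runs of a profile (blank icodes, +1 steps).
profile_segments <- function(profile) {
  n <- length(profile$number)
  if (n == 0) return(list())
  brk <- c(TRUE, diff(profile$number) != 1L | profile$icode[-1] != "" |
             profile$icode[-n] != "")
  unname(split(seq_len(n), cumsum(brk)))
}

#' Assign a chain to a target sequence
#'
#' The longest continuous segment of the chain (capped at
#' \code{max_assign_length} residues) is aligned, without gaps, against every
#' target; the chain is assigned when the best alignment's p-value falls
#' below the threshold. Chains shorter than \code{min_chain_length} are
#' skipped, not failed.
#'
#' @param profile a \code{residue_profile}.
#' @param sequences list of \code{target_sequence} objects.
#' @param config a \code{scan_config}.
#' @return a \code{chain_assignment} list: \code{chain_id}, \code{seq_id},
#'   \code{pvalue}, \code{assigned}, \code{skipped} and (when attempted) the
#'   aligned segment indices and offset.
#' @export
assign_chain <- function(profile, sequences, config = scan_config()) {
  n <- length(profile$number)
  if (n < config$min_chain_length)
    return(structure(list(chain_id = profile$chain_id, seq_id = NA_character_,
                          pvalue = NA_real_, assigned = FALSE, skipped = TRUE,
                          reason = "below minimum length"),
                     class = "chain_assignment"))
  segs <- profile_segments(profile)
  seg <- segs[[which.max(lengths(segs))]]
  if (length(seg) > config$max_assign_length)
    seg <- seg[seq_len(config$max_assign_length)]
  best <- tryCatch(
    window_alignment(profile_rows(profile, seg), sequences, config$align),
    error = function(e) NULL)
  if (is.null(best))
    return(structure(list(chain_id = profile$chain_id, seq_id = NA_character_,
                          pvalue = NA_real_, assigned = FALSE,
                          skipped = FALSE, reason = "no sequence long enough"),
                     class = "chain_assignment"))
  structure(list(chain_id = profile$chain_id, seq_id = best$seq_id,
                 pvalue = best$pvalue,
                 assigned = best$pvalue < config$pvalue_threshold,
                 skipped = FALSE, segment = seg, offset = best$offset,
                 score = best$score),
            class = "chain_assignment")
}

# Minimum-Hamming anchor of a claimed one-letter string in the target
# ('X' is a wildcard on either side). Ties prefer the offset closest to the
# numbering-implied position, then the smallest offset. Returns the 0-based
# offset, or NA when more than half the letters disagree everywhere.
anchor_offset <- function(claimed, target, implied = 0L) {
  cl <- strsplit(claimed, "")[[1]]
  tl <- strsplit(target, "")[[1]]
  m <- length(cl); n <- length(tl)
  if (m > n) return(NA_integer_)
  offs <- 0:(n - m)
  mism <- vapply(offs, function(o) {
    tt <- tl[o + seq_len(m)]
    sum(cl != tt & cl != "X" & tt != "X")
  }, numeric(1))
  best <- min(mism)
  if (best > m / 2) return(NA_integer_)
  cand <- offs[mism == best]
  cand[order(abs(cand - implied), cand)][1]
}

#' Scan an assigned chain with sliding windows
#'
#' Windows are taken only inside continuous residue-numbering runs. For each
#' window the best gapless re-alignment against the assigned target is
#' compared with the register the model claims (one minimum-Hamming anchor
#' per segment, advanced with the numbering).
#'
#' @param profile a \code{residue_profile} of the chain.
#' @param chain the corresponding chain of a \code{structure_model}.
#' @param sequences list of \code{target_sequence} objects.
#' @param assignment the chain's \code{chain_assignment}; must be assigned.
#' @param config a \code{scan_config}.
#' @return data frame of window calls: residue-number span, best offset,
#'   score, p-value, the model-implied offset, their difference
#'   (\code{delta}) and a status in \{consistent, shifted, inconclusive\}.
#' @export
scan_chain <- function(profile, chain, sequences, assignment,
                       config = scan_config()) {
  if (!isTRUE(assignment$assigned))
    stop("chain ", profile$chain_id,
         " is not assigned to a target; report it as unassigned_chain")
  target <- NULL
  for (s in sequences) if (s$id == assignment$seq_id) target <- s
  if (is.null(target)) stop("assigned sequence '", assignment$seq_id,
                            "' not among the targets")
  ms <- model_sequence(chain)
  if (length(profile$number) != length(chain$residues) ||
      any(profile$number != ms$numbers))
    stop("profile rows do not match chain ", chain$id, " residues")
  type1 <- strsplit(ms$sequence, "")[[1]]

  calls <- list()
  for (seg in profile_segments(profile)) {
    seg_len <- length(seg)
    l <- config$window_length
    if (seg_len < l) {
      if (seg_len < config$min_chain_length) next
      l <- seg_len  # single truncated window
    }
    claimed <- paste(type1[seg], collapse = "")
    implied <- profile$number[seg[1]] - 1L
    base <- anchor_offset(claimed, target$residues, implied)

    lr <- log_odds(profile_rows(profile, seg), config$align)
    seq_idx <- seq_to_index(target$residues)
    nt <- length(seq_idx)
    if (nt < l) next
    sc <- segment_window_scores(lr, seq_idx, l)
    starts <- seq(1L, nrow(sc$scores), by = config$step)
    best_off <- max.col(sc$scores[starts, , drop = FALSE],
                        ties.method = "first") - 1L
    best_score <- sc$scores[cbind(starts, best_off + 1L)]
    n_off <- ncol(sc$scores)

    bins_all <- matrix(as.integer(floor(lr[, 1:20, drop = FALSE] /
                                          config$align$grid_step + 1e-9)),
                       nrow = seg_len)
    pvals <- vapply(seq_along(starts), function(k) {
      j <- starts[k]
      null <- null_distribution_from_bins(bins_all[j:(j + l - 1L), ,
                                                   drop = FALSE],
                                          config$align)
      alignment_pvalue(best_score[k], null, n_off)
    }, numeric(1))

    model_offset <- if (is.na(base)) rep(NA_integer_, length(starts)) else
      base + starts - 1L
    delta <- best_off - model_offset
    status <- ifelse(pvals >= config$pvalue_threshold, "inconclusive",
                     ifelse(!is.na(delta) & delta == 0L, "consistent",
                            "shifted"))
    calls[[length(calls) + 1L]] <- data.frame(
      chain = profile$chain_id,
      start = profile$number[seg[starts]],
      end = profile$number[seg[starts + l - 1L]],
      window_length = l, segment = seg[1], seg_pos = starts,
      seq_id = target$id, offset = best_off, score = best_score,
      pvalue = pvals, model_offset = model_offset, delta = delta,
      status = status, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0)
    return(data.frame(chain = character(0), start = integer(0),
                      end = integer(0), window_length = integer(0),
                      segment = integer(0), seg_pos = integer(0),
                      seq_id = character(0), offset = integer(0),
                      score = numeric(0), pvalue = numeric(0),
                      model_offset = integer(0), delta = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Region bounds from a merged run of shifted windows
#'
#' Half a window is trimmed from each side: the first shifted window places
#' the region start at its midpoint, the last at its midpoint, so a run of
#' shifted windows maps onto the residue span that actually changed
#' register. Degenerate (single-window) runs collapse to the midpoint.
#'
#' @param first_start residue number starting the first shifted window.
#' @param last_end residue number ending the last shifted window.
#' @param window_length window length in residues.
#' @return integer vector \code{c(start, end)} in residue numbers.
#' @export
region_bounds <- function(first_start, last_end, window_length) {
  half <- window_length %/% 2L
  start <- first_start + half
  end <- last_end - half
  if (end < start) end <- start
  c(start = start, end = end)
}

#' Merge window calls into categorized issue regions
#'
#' Shifted windows with equal register offset are merged (tolerating
#' \code{merge_gap} residues of separation); a merged region whose claimed
#' residues match the target at the detected offset is an indexing issue
#' (numbering wrong, identities right), otherwise a register shift. Isolated
#' claimed-versus-target letter disagreements (or unknown \code{X} residues)
#' inside consistent coverage become sequence-mismatch regions.
#'
#' @param calls window-call data frame from [scan_chain()], ordered by start.
#' @param chain the scanned chain.
#' @param target the assigned \code{target_sequence}.
#' @param config a \code{scan_config}.
#' @return data frame of issue regions: \code{chain}, \code{category},
#'   \code{start}, \code{end}, \code{offset}, \code{best_pvalue},
#'   \code{n_windows}.
#' @export
categorize_calls <- function(calls, chain, target, config = scan_config()) {
  regions <- list()
  ms <- model_sequence(chain)
  type1 <- strsplit(ms$sequence, "")[[1]]
  tl <- strsplit(target$residues, "")[[1]]
  num2idx <- stats::setNames(seq_along(ms$numbers), ms$numbers)

  sh <- calls[calls$status == "shifted" & !is.na(calls$delta), , drop = FALSE]
  if (nrow(sh) > 0) {
    sh <- sh[order(sh$segment, sh$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, sh$delta[-1] != sh$delta[-nrow(sh)] |
                      sh$segment[-1] != sh$segment[-nrow(sh)] |
                      sh$start[-1] - sh$end[-nrow(sh)] - 1L > config$merge_gap))
    for (g in split(seq_len(nrow(sh)), grp)) {
      blk <- sh[g, , drop = FALSE]
      b <- region_bounds(blk$start[1], blk$end[nrow(blk)],
                         blk$window_length[1])
      delta <- blk$delta[1]
      # claimed letters across the region vs target at the detected register
      ridx <- num2idx[as.character(b["start"]:b["end"])]
      ridx <- ridx[!is.na(ridx)]
      i0 <- num2idx[as.character(blk$start[1])]
      tpos <- blk$model_offset[1] + (ridx - i0) + delta  # 0-based target pos
      ok <- tpos >= 0 & tpos < length(tl)
      cl <- type1[ridx[ok]]
      tt <- tl[tpos[ok] + 1L]
      identities_right <- length(cl) > 0 &&
        all(cl == tt | cl == "X" | tt == "X")
      regions[[length(regions) + 1L]] <- data.frame(
        chain = blk$chain[1],
        category = if (identities_right) "indexing_issue" else "register_shift",
        start = unname(b["start"]), end = unname(b["end"]),
        offset = delta, best_pvalue = min(blk$pvalue),
        n_windows = nrow(blk), stringsAsFactors = FALSE)
    }
  }

  # sequence mismatches inside consistent coverage
  cons <- calls[calls$status == "consistent", , drop = FALSE]
  if (nrow(cons) > 0) {
    mm_num <- integer(0); mm_p <- numeric(0)
    seen <- new.env(parent = emptyenv())
    for (w in seq_len(nrow(cons))) {
      nums <- cons$start[w]:cons$end[w]
      tpos <- cons$model_offset[w] + seq_along(nums) - 1L  # 0-based
      for (k in seq_along(nums)) {
        key <- as.character(nums[k])
        if (!is.null(get0(key, envir = seen))) next
        assign(key, TRUE, envir = seen)
        ci <- num2idx[key]
        if (is.na(ci) || tpos[k] < 0 || tpos[k] >= length(tl)) next
        if (type1[ci] != tl[tpos[k] + 1L] || type1[ci] == "X") {
          mm_num <- c(mm_num, nums[k]); mm_p <- c(mm_p, cons$pvalue[w])
        }
      }
    }
    if (length(mm_num) > 0) {
      o <- order(mm_num); mm_num <- mm_num[o]; mm_p <- mm_p[o]
      grp <- cumsum(c(TRUE, diff(mm_num) > 1L))
      for (g in split(seq_along(mm_num), grp)) {
        regions[[length(regions) + 1L]] <- data.frame(
          chain = calls$chain[1], category = "sequence_mismatch",
          start = mm_num[g[1]], end = mm_num[g[length(g)]],
          offset = NA_integer_, best_pvalue = min(mm_p[g]),
          n_windows = length(g), stringsAsFactors = FALSE)
      }
    }
  }

  if (length(regions) == 0)
    return(empty_regions())
  out <- do.call(rbind, regions)
  out[order(out$start, out$category), , drop = FALSE]
}

empty_regions <- function() {
  data.frame(chain = character(0), category = character(0),
             start = integer(0), end = integer(0), offset = integer(0),
             best_pvalue = numeric(0), n_windows = integer(0),
             stringsAsFactors = FALSE)
}
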