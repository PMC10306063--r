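# Residue-type probability profiles: container and tab-separated persistence.

#' Construct a residue profile
#'
#' @param chain_id chain identifier the rows belong to.
#' @param number integer author residue numbers, in chain order.
#' @param icode insertion codes (blank when absent).
#' @param probs n x 20 matrix of class probabilities, columns in fixed
#'   alphabetical one-letter order \code{A, C, D, ..., Y}; every row must be
#'   non-negative and sum to 1 (within 1e-9 of it; rows are renormalized).
#' @param flagged logical vector marking rows that fell back to uniform.
#' @return object of class \code{residue_profile}.
#' @export
residue_profile <- function(chain_id, number, icode = NULL, probs,
                            flagged = NULL) {
  n <- length(number)
  if (is.null(icode)) icode <- rep("", n)
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == n, ncol(probs) == 20,
            length(icode) == n, length(flagged) == n)
  if (any(probs < 0)) stop("negative probability in profile row ",
                           which(apply(probs < 0, 1, any))[1])
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("profile row ", which(abs(rs - 1) > 1e-9)[1],
         " does not sum to 1 (sum = ", rs[which(abs(rs - 1) > 1e-9)[1]], ")")
  probs <- probs / rs
  dimnames(probs) <- list(NULL, AA1)
  structure(list(chain_id = chain_id, number = as.integer(number),
                 icode = icode, probs = probs, flagged = flagged),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("residue_profile: chain %s, %d residues (%d flagged)\n",
              x$chain_id, length(x$number), sum(x$flagged)))
  invisible(x)
}

#' @export
length.residue_profile <- function(x) length(x$number)

# Subset profile rows (used by the window scanner).
profile_rows <- function(profile, idx) profile$probs[idx, , drop = FALSE]

#' Write residue profiles to a tab-separated table
#'
#' Columns: \code{chain}, \code{resnum}, \code{icode}, then the 20 class
#' probabilities in fixed \code{A..Y} order.
#'
#' @param profiles a \code{residue_profile} or list of them.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_profile <- function(profiles, path) {
  if (inherits(profiles, "residue_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    data.frame(chain = p$chain_id, resnum = p$number,
               icode = ifelse(nzchar(p$icode), p$icode, "."),
               p$probs, check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read residue profiles from a tab-separated table
#'
#' @param path a table written by [write_profile()].
#' @return named list of \code{residue_profile} objects, one per chain.
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(chain = "character",
                                          icode = "character"))
  need <- c("chain", "resnum", "icode", AA1)
  if (!all(need %in% colnames(tab)))
    stop("profile table lacks columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  out <- list()
  for (cid in unique(tab$chain)) {
    sub <- tab[tab$chain == cid, , drop = FALSE]
    out[[cid]] <- residue_profile(
      cid, number = sub$resnum,
      icode = ifelse(sub$icode == ".", "", sub$icode),
      probs = as.matrix(sub[, AA1]))
  }
  out
}
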