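# On-disk synthetic benchmark bundles: FASTA targets, profile table, claimed
# assignment table and ground-truth JSON, all plain text.

#' Write a synthetic benchmark bundle to a directory
#'
#' @param bench a benchmark from [make_benchmark()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequences(list(bench$target), file.path(dir, "targets.fasta"))
  write_profile(bench$profile, file.path(dir, "profile.tsv"))
  ms <- model_sequence(bench$chain)
  claimed <- data.frame(chain = bench$chain$id, resnum = ms$numbers,
                        icode = ".", type1 = strsplit(ms$sequence, "")[[1]],
                        stringsAsFactors = FALSE)
  utils::write.table(claimed, file.path(dir, "claimed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- bench$truth
  jsonlite::write_json(
    list(target_id = truth$target_id, true_pos = truth$true_pos,
         numbers = truth$numbers, regions = truth$regions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a synthetic benchmark bundle
#'
#' @param dir a directory written by [write_benchmark()].
#' @return list with \code{target}, \code{chain}, \code{truth} and
#'   \code{profile}, mirroring [make_benchmark()].
#' @export
read_benchmark <- function(dir) {
  target <- read_sequences(file.path(dir, "targets.fasta"))[[1]]
  profile <- read_profile(file.path(dir, "profile.tsv"))[[1]]
  claimed <- utils::read.delim(file.path(dir, "claimed.tsv"),
                               colClasses = c(chain = "character",
                                              icode = "character",
                                              type1 = "character"))
  residues <- lapply(seq_len(nrow(claimed)), function(i)
    new_residue(claimed$resnum[i],
                ifelse(claimed$icode[i] == ".", "", claimed$icode[i]),
                aa_one_to_three(claimed$type1[i]),
                matrix(numeric(0), ncol = 3)))
  chain <- new_chain(claimed$chain[1], residues)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  regions <- tj$regions
  if (is.null(regions) || length(regions) == 0)
    regions <- empty_regions()[, c("chain", "category", "start", "end",
                                   "offset")]
  truth <- structure(list(true_pos = as.integer(tj$true_pos),
                          numbers = as.integer(tj$numbers),
                          target_id = tj$target_id,
                          regions = regions),
                     class = "ground_truth")
  list(target = target, chain = chain, truth = truth, profile = profile)
}
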