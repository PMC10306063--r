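# End-to-end validation and reporting.

REPORT_SCHEMA_VERSION <- "1.0"
ISSUE_CATEGORIES <- c("register_shift", "indexing_issue", "sequence_mismatch",
                      "unassigned_chain")

#' Validate the sequence assignment of a protein model
#'
#' Full pipeline: per-residue probability profiles (from a density map via
#' the pluggable classifier, or supplied precomputed), chain-to-sequence
#' assignment, sliding-window register scanning, and categorized issue
#' regions.
#'
#' @param model a \code{structure_model} or path to a PDB/mmCIF file.
#' @param sequences list of \code{target_sequence} objects or path to a
#'   FASTA file.
#' @param map a \code{density_map}, or path to a CCP4/MRC map or MTZ file;
#'   exactly one of \code{map} and \code{profiles} must be given.
#' @param profiles precomputed profiles: a named list of
#'   \code{residue_profile} objects (names = chain ids) or path to a profile
#'   table written by [write_profile()].
#' @param config a \code{scan_config}.
#' @param classifier optional classifier override for [extract_profile()].
#' @param labels optional MTZ column labels \code{c(F, PHI)}.
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic; the seed is exposed for provenance).
#' @return an object of class \code{seqcheck_report}: per-chain assignments,
#'   issue regions, category counts and run metadata.
#' @export
check_sequence <- function(model, sequences, map = NULL, profiles = NULL,
                           config = scan_config(), classifier = NULL,
                           labels = NULL, seed = NULL) {
  inputs <- list()
  if (is.character(model)) {
    inputs$model <- model
    model <- read_structure(model)
  }
  if (is.character(sequences)) {
    inputs$sequences <- sequences
    sequences <- read_sequences(sequences)
  }
  if (is.null(map) == is.null(profiles))
    stop("provide exactly one density source: map/mtz or profiles")
  if (!is.null(map) && is.character(map)) {
    inputs$density <- map
    map <- read_density(map, labels = labels)
  }
  if (!is.null(profiles) && is.character(profiles)) {
    inputs$profiles <- profiles
    profiles <- read_profile(profiles)
  }

  chain_info <- list()
  regions <- empty_regions()
  for (ch in model$chains) {
    profile <- if (!is.null(profiles)) profiles[[ch$id]] else
      extract_profile(model, map, ch$id, classifier = classifier)
    if (is.null(profile)) {
      chain_info[[ch$id]] <- list(chain_id = ch$id, n_residues =
                                    length(ch$residues), status = "skipped",
                                  reason = "no profile for chain")
      next
    }
    asn <- assign_chain(profile, sequences, config)
    info <- list(chain_id = ch$id, n_residues = length(ch$residues))
    if (isTRUE(asn$skipped)) {
      info$status <- "skipped"
      info$reason <- asn$reason
    } else if (!asn$assigned) {
      info$status <- "unassigned"
      info$pvalue <- asn$pvalue
      regions <- rbind(regions, data.frame(
        chain = ch$id, category = "unassigned_chain",
        start = ch$residues[[1]]$number,
        end = ch$residues[[length(ch$residues)]]$number,
        offset = NA_integer_,
        best_pvalue = if (is.null(asn$pvalue)) NA_real_ else asn$pvalue,
        n_windows = 0L, stringsAsFactors = FALSE))
    } else {
      info$status <- "assigned"
      info$seq_id <- asn$seq_id
      info$pvalue <- asn$pvalue
      calls <- scan_chain(profile, ch, sequences, asn, config)
      target <- sequences[[which(vapply(sequences, `[[`, character(1), "id")
                                 == asn$seq_id)]]
      regions <- rbind(regions, categorize_calls(calls, ch, target, config))
      info$n_windows <- nrow(calls)
    }
    chain_info[[ch$id]] <- info
  }

  counts <- vapply(ISSUE_CATEGORIES, function(k)
    sum(regions$category == k), integer(1))
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    chains = chain_info,
    regions = regions,
    summary = as.list(counts),
    meta = list(
      tool = "seqregister",
      version = as.character(utils::packageVersion("seqregister")),
      window_length = config$window_length, step = config$step,
      pvalue_threshold = config$pvalue_threshold,
      min_chain_length = config$min_chain_length,
      merge_gap = config$merge_gap,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      input_hashes = if (length(inputs))
        as.list(tools::md5sum(unlist(inputs))) else list())),
    class = "seqcheck_report")
}

#' @export
print.seqcheck_report <- function(x, ...) {
  cat("seqregister validation report\n")
  for (info in x$chains) {
    line <- switch(info$status,
      assigned = sprintf("chain %s: %d residues, assigned to %s (p = %.3g)",
                         info$chain_id, info$n_residues, info$seq_id,
                         info$pvalue),
      unassigned = sprintf("chain %s: %d residues, NOT assigned (p = %.3g)",
                           info$chain_id, info$n_residues,
                           if (is.null(info$pvalue) || is.na(info$pvalue)) 1
                           else info$pvalue),
      skipped = sprintf("chain %s: %d residues, skipped (%s)",
                        info$chain_id, info$n_residues, info$reason))
    cat(" ", line, "\n")
  }
  if (nrow(x$regions) == 0) {
    cat("  no sequence-assignment issues detected\n")
  } else {
    for (i in seq_len(nrow(x$regions))) cat("  ", region_text(x$regions[i, ]),
                                            "\n", sep = "")
  }
  invisible(x)
}

region_text <- function(r) {
  label <- switch(r$category,
                  register_shift = sprintf("register shift %+d", r$offset),
                  indexing_issue = sprintf("indexing issue %+d", r$offset),
                  sequence_mismatch = "sequence mismatch",
                  unassigned_chain = "chain not assigned to any target")
  p <- if (is.na(r$best_pvalue)) "" else
    sprintf(", p < %.2g", max(r$best_pvalue, 1e-300))
  sprintf("chain %s, residues %d-%d, %s%s", r$chain, r$start, r$end, label, p)
}

#' @export
summary.seqcheck_report <- function(object, ...) {
  cat("issue regions by category:\n")
  for (k in names(object$summary))
    cat(sprintf("  %-18s %d\n", k, object$summary[[k]]))
  invisible(object$summary)
}

#' Write a validation report to disk
#'
#' @param report a \code{seqcheck_report}.
#' @param path output path.
#' @param format \code{"json"} (schema-stable, lossless) or \code{"text"}
#'   (human-readable rendering).
#' @return invisibly, \code{path}.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Read a JSON validation report
#'
#' @param path a file written by [write_report()] with JSON format.
#' @return a \code{seqcheck_report}.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- x$regions
  if (is.null(regions) || length(regions) == 0 || nrow(regions) == 0)
    regions <- empty_regions()
  regions$offset <- as.integer(regions$offset)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$n_windows <- as.integer(regions$n_windows)
  x$regions <- regions
  x$summary <- lapply(x$summary, as.integer)
  structure(x, class = "seqcheck_report")
}

#' Run the full validation from file paths
#'
#' Thin orchestration used by the command-line interface: reads the inputs,
#' runs [check_sequence()] and optionally writes JSON/text reports.
#'
#' @param model_path coordinates (PDB/mmCIF).
#' @param seq_path target sequences (FASTA).
#' @param map_path CCP4/MRC map or MTZ coefficients (exclusive with
#'   \code{profile_path}).
#' @param profile_path precomputed profile table (exclusive with
#'   \code{map_path}).
#' @param config a \code{scan_config}.
#' @param labels optional MTZ labels \code{c(F, PHI)}.
#' @param seed integer seed recorded in the report.
#' @param json_out,txt_out optional output paths.
#' @return the \code{seqcheck_report}, invisibly when writing output.
#' @export
run_validation <- function(model_path, seq_path, map_path = NULL,
                           profile_path = NULL, config = scan_config(),
                           labels = NULL, seed = NULL, json_out = NULL,
                           txt_out = NULL) {
  report <- check_sequence(model = model_path, sequences = seq_path,
                           map = map_path, profiles = profile_path,
                           config = config, labels = labels, seed = seed)
  if (!is.null(json_out)) write_report(report, json_out, "json")
  if (!is.null(txt_out)) write_report(report, txt_out, "text")
  if (is.null(json_out) && is.null(txt_out)) report else invisible(report)
}
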