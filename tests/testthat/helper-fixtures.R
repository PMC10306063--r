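# Fixtures are built in code at test time; nothing binary ships with the
# package.

aa1 <- seqregister:::AA1

# A minimal two-chain model: 30 ALA in chain A, 10 GLY in chain B, with a
# stub backbone per residue.
toy_two_chain_model <- function(unk_at = NULL, icode_at = NULL,
                                gap_after = NULL) {
  mk_chain <- function(id, n, type3, offset_y) {
    residues <- lapply(seq_len(n), function(i) {
      at <- rbind(N = c(3 * i - 1, offset_y, 10),
                  CA = c(3 * i, offset_y, 10),
                  C = c(3 * i + 1, offset_y, 10),
                  O = c(3 * i + 1, offset_y + 1, 10))
      t3 <- if (!is.null(unk_at) && id == "A" && i == unk_at) "UNK" else type3
      ic <- if (!is.null(icode_at) && id == "A" && i == icode_at) "A" else ""
      num <- i
      if (!is.null(gap_after) && id == "A" && i > gap_after) num <- i + 4L
      seqregister:::new_residue(num, ic, t3, at)
    })
    seqregister:::new_chain(id, residues)
  }
  chains <- list(A = mk_chain("A", 30, "ALA", 10),
                 B = mk_chain("B", 10, "GLY", 20))
  seqregister:::new_structure_model(chains, c(120, 40, 20, 90, 90, 90))
}

# mmCIF rendering of a structure_model (test-only writer used to check
# cross-format parsing).
write_toy_cif <- function(model, path) {
  rows <- character(0)
  i <- 0L
  for (ch in model$chains) for (r in ch$residues) {
    at <- r$atoms
    for (a in seq_len(nrow(at))) {
      i <- i + 1L
      ic <- if (nzchar(r$icode)) r$icode else "?"
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 10.00 %d %s %s %s 1",
        i, substr(rownames(at)[a], 1, 1), rownames(at)[a], r$type3, ch$id,
        r$number, ic, at[a, 1], at[a, 2], at[a, 3], r$number, r$type3,
        ch$id, rownames(at)[a]))
    }
  }
  writeLines(c(
    "data_toy",
    sprintf("_cell.length_a %.3f", model$cell$a),
    sprintf("_cell.length_b %.3f", model$cell$b),
    sprintf("_cell.length_c %.3f", model$cell$c),
    sprintf("_cell.angle_alpha %.2f", model$cell$alpha),
    sprintf("_cell.angle_beta %.2f", model$cell$beta),
    sprintf("_cell.angle_gamma %.2f", model$cell$gamma),
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num", rows), path)
  path
}

# Chain listing used for cross-format comparisons.
chain_listing <- function(model) {
  lapply(model$chains, function(ch)
    data.frame(number = vapply(ch$residues, `[[`, integer(1), "number"),
               icode = vapply(ch$residues, `[[`, character(1), "icode"),
               type3 = vapply(ch$residues, `[[`, character(1), "type3"),
               stringsAsFactors = FALSE))
}

# Degenerate window whose rows put all floor-able mass on the letters of a
# subsequence (forces a unique best alignment at the construction offset).
degenerate_window <- function(letters) {
  w <- matrix(0, length(letters), 20, dimnames = list(NULL, aa1))
  for (i in seq_along(letters)) w[i, letters[i]] <- 1
  w
}

# Seeded random probability window.
random_window <- function(l, seed) {
  seqregister:::with_seed(seed, {
    w <- matrix(stats::rexp(l * 20), l, 20, dimnames = list(NULL, aa1))
    sweep(w, 1, rowSums(w), `/`)
  })
}

# Brute-force alignment scan: direct per-offset re-scoring.
exhaustive_best <- function(window, sequences, params) {
  l <- nrow(window)
  best <- NULL
  for (s in sequences) {
    n <- nchar(s$residues)
    if (n < l) next
    for (o in 0:(n - l)) {
      sc <- alignment_score(window, s, o, params)
      if (is.null(best) || sc > best$score)
        best <- list(seq_id = s$id, offset = o, score = sc)
    }
  }
  best
}

# Ground-truth scaffold without injected errors (n residues of a target).
plain_truth <- function(n) {
  structure(list(true_pos = seq_len(n), numbers = seq_len(n),
                 target_id = "t", regions = seqregister:::empty_regions()),
            class = "ground_truth")
}

scan_benchmark <- function(bench, cfg = scan_config()) {
  asn <- assign_chain(bench$profile, list(bench$target), cfg)
  if (!isTRUE(asn$assigned)) return(list(assignment = asn, regions = NULL))
  calls <- scan_chain(bench$profile, bench$chain, list(bench$target), asn, cfg)
  list(assignment = asn, calls = calls,
       regions = categorize_calls(calls, bench$chain, bench$target, cfg))
}
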