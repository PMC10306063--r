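# Coordinate and sequence input/output.
#
# Coordinates are parsed with bio3d (PDB and mmCIF); the unit cell and space
# group, which bio3d does not expose, are scanned from the file directly.
# All coordinates are carried in orthogonal angstroms.

STANDARD_AA3 <- unname(AA3)

#' Read a protein model from a PDB or mmCIF file
#'
#' Alternate conformations are reduced to altloc 'A' (or blank); residues are
#' ordered by (number, insertion code) within each chain. Non-protein residues
#' (waters, ligands) are retained in the \code{hetero} table and flagged, not
#' mixed into the protein chains.
#'
#' @param path path to a \code{.pdb}/\code{.ent} or \code{.cif} file; the
#'   format is detected from the extension, falling back to content sniffing.
#' @return an object of class \code{structure_model}: a list with
#'   \code{chains} (named list; each chain has \code{id} and a list of
#'   \code{residues} with \code{number}, \code{icode}, \code{type3},
#'   \code{type1} and an atom coordinate matrix), \code{cell},
#'   \code{spacegroup} and \code{hetero}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- detect_structure_format(path)
  parsed <- tryCatch(
    if (fmt == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", basename(path), " as ", fmt,
                             ": ", conditionMessage(e), call. = FALSE))
  atoms <- parsed$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms <- atoms[atoms$alt %in% c("", "A"), , drop = FALSE]
  atoms$chain[is.na(atoms$chain)] <- " "

  is_protein <- toupper(atoms$resid) %in% c(STANDARD_AA3, "UNK", "MSE")
  prot <- atoms[is_protein, , drop = FALSE]
  het <- atoms[!is_protein, , drop = FALSE]

  chains <- list()
  for (cid in unique(prot$chain)) {
    ca <- prot[prot$chain == cid, , drop = FALSE]
    key <- paste(ca$resno, ca$insert)
    res_keys <- unique(key)
    residues <- vector("list", length(res_keys))
    for (i in seq_along(res_keys)) {
      ra <- ca[key == res_keys[i], , drop = FALSE]
      xyz <- cbind(ra$x, ra$y, ra$z)
      rownames(xyz) <- ra$elety
      if (any(!is.finite(xyz)))
        stop("non-finite coordinates in chain ", cid, " residue ", ra$resno[1])
      type3 <- toupper(ra$resid[1])
      if (type3 == "MSE") type3 <- "MET"  # selenomethionine read as MET
      residues[[i]] <- new_residue(ra$resno[1], ra$insert[1], type3, xyz)
    }
    chains[[cid]] <- new_chain(cid, residues)
  }
  if (length(chains) == 0)
    stop("no protein chains in ", basename(path))

  geom <- read_cell_info(path, fmt)
  new_structure_model(chains, cell = geom$cell, spacegroup = geom$spacegroup,
                      hetero = het)
}

detect_structure_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|^loop_|^_atom_site\\.", head_lines))) "cif" else "pdb"
}

read_cell_info <- function(path, fmt) {
  lines <- readLines(path, warn = FALSE)
  cell <- NULL; sg <- "P 1"
  if (fmt == "pdb") {
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (length(cl) >= 1) {
      f <- function(i, j) suppressWarnings(as.numeric(substr(cl[1], i, j)))
      vals <- c(f(7, 15), f(16, 24), f(25, 33), f(34, 40), f(41, 47), f(48, 54))
      if (all(is.finite(vals)) && all(vals[1:3] > 0)) {
        cell <- as_cell(vals)
        s <- trimws(substr(cl[1], 56, 66))
        if (nzchar(s)) sg <- s
      }
    }
  } else {
    grab <- function(tag) {
      m <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (length(m) == 0) return(NA_real_)
      suppressWarnings(as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][2]))
    }
    vals <- c(grab("_cell\\.length_a"), grab("_cell\\.length_b"),
              grab("_cell\\.length_c"), grab("_cell\\.angle_alpha"),
              grab("_cell\\.angle_beta"), grab("_cell\\.angle_gamma"))
    if (all(is.finite(vals)) && all(vals[1:3] > 0)) cell <- as_cell(vals)
    m <- grep("_symmetry\\.space_group_name_H-M", lines, value = TRUE)
    if (length(m) >= 1) {
      s <- sub(".*space_group_name_H-M\\s+", "", m[1])
      s <- gsub("['\"]", "", s)
      if (nzchar(trimws(s))) sg <- trimws(s)
    }
  }
  if (is.null(cell)) cell <- as_cell(c(1, 1, 1, 90, 90, 90))
  list(cell = cell, spacegroup = sg)
}

new_residue <- function(number, icode, type3, atoms) {
  type3 <- toupper(type3)
  list(number = as.integer(number), icode = icode, type3 = type3,
       type1 = aa_three_to_one(type3), atoms = atoms)
}

new_chain <- function(id, residues) {
  num <- vapply(residues, function(r) r$number, integer(1))
  ico <- vapply(residues, function(r) r$icode, character(1))
  ord <- order(num, ico)
  residues <- residues[ord]
  key <- paste(num[ord], ico[ord])
  if (anyDuplicated(key))
    stop("chain ", id, ": duplicate residue (number, icode): ",
         key[duplicated(key)][1])
  list(id = id, residues = residues)
}

new_structure_model <- function(chains, cell, spacegroup = "P 1",
                                hetero = NULL) {
  structure(list(chains = chains, cell = as_cell(cell),
                 spacegroup = spacegroup, hetero = hetero),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", length(x$chains), "protein chain(s)\n")
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues\n", ch$id, length(ch$residues)))
  cat(sprintf("  cell: %.2f %.2f %.2f  %.1f %.1f %.1f  (%s)\n",
              x$cell$a, x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta,
              x$cell$gamma, x$spacegroup))
  invisible(x)
}

#' Write a protein model to a PDB file
#'
#' @param model a \code{structure_model}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_structure <- function(model, path) {
  rows <- list()
  for (ch in model$chains) {
    for (r in ch$residues) {
      xyz <- r$atoms
      rows[[length(rows) + 1L]] <- data.frame(
        elety = rownames(xyz), resid = r$type3, chain = ch$id,
        resno = r$number, insert = r$icode,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, NA),
                   elety = at$elety)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   model$cell$a, model$cell$b, model$cell$c, model$cell$alpha,
                   model$cell$beta, model$cell$gamma, model$spacegroup)
  body <- readLines(path, warn = FALSE)
  writeLines(c(cryst, body), path)
  invisible(path)
}

#' Read target sequences from a FASTA file
#'
#' Lowercase residues are upcased and trailing \code{*} terminators stripped.
#' Identifiers must be unique and residues restricted to the 20 standard
#' one-letter codes plus \code{X}.
#'
#' @param path FASTA file with at least one record.
#' @return list of \code{target_sequence} objects (\code{id}, \code{residues}).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", basename(path),
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0) stop("no sequence records in ", basename(path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    s <- sub("\\*+$", "", s)
    out[[i]] <- target_sequence(ids[i], s)
  }
  out
}

#' Construct a target sequence
#'
#' @param id identifier.
#' @param residues one-letter amino-acid string (standard 20 plus \code{X}).
#' @return a \code{target_sequence} object.
#' @export
target_sequence <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("sequence ", id, " is empty")
  letters_ok <- strsplit(residues, "")[[1]] %in% c(AA1, "X")
  if (!all(letters_ok))
    stop("illegal residue letter '",
         strsplit(residues, "")[[1]][which(!letters_ok)[1]],
         "' in sequence '", id, "' at position ", which(!letters_ok)[1])
  structure(list(id = id, residues = residues), class = "target_sequence")
}

#' Write target sequences to a FASTA file
#'
#' @param sequences list of \code{target_sequence} objects.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_sequences <- function(sequences, path) {
  lines <- unlist(lapply(sequences, function(s) {
    body <- gsub(sprintf("(.{1,%d})", 60L), "\\1\n", s$residues)
    c(paste0(">", s$id), strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Modelled sequence of a chain
#'
#' @param chain a chain from a \code{structure_model}.
#' @return list with \code{sequence} (one-letter string, \code{X} for unknown
#'   residues), \code{numbers} (author residue numbers) and \code{continuous}
#'   (\code{TRUE} iff the numbering spans exactly the residue count and no
#'   insertion codes are present).
#' @export
model_sequence <- function(chain) {
  if (length(chain$residues) == 0) stop("chain ", chain$id, " is empty")
  type1 <- vapply(chain$residues, function(r) r$type1, character(1))
  num <- vapply(chain$residues, function(r) r$number, integer(1))
  ico <- vapply(chain$residues, function(r) r$icode, character(1))
  continuous <- all(ico == "") &&
    (num[length(num)] - num[1] + 1L == length(num))
  list(sequence = paste(type1, collapse = ""), numbers = num,
       continuous = continuous)
}

# Maximal runs of residues with consecutive numbering and blank insertion
# codes. Returns a list of integer index vectors into chain$residues.
continuous_segments <- function(chain) {
  num <- vapply(chain$residues, function(r) r$number, integer(1))
  ico <- vapply(chain$residues, function(r) r$icode, character(1))
  n <- length(num)
  if (n == 0) return(list())
  # break before residue i if numbering jumps or an insertion code flanks it
  brk <- c(TRUE, diff(num) != 1L | ico[-1] != "" | ico[-n] != "")
  grp <- cumsum(brk)
  unname(split(seq_len(n), grp))
}

chain_from_model <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("chain '", chain_id, "' not present in model")
  ch
}
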