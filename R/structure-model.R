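#' Structure models
#'
#' A `structure_model` is a light container for the coordinates the
#' structural-analysis kernels need: an atom table (chain, residue number
#' and name, atom name, element, x/y/z in Angstrom) plus optional per-chain
#' IMGT annotations added by [annotate_structure()].  Only the first model
#' of multi-model files is kept, alternate location `"A"` is preferred and
#' hydrogens are dropped.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, need]
  atoms$resno <- as.integer(atoms$resno)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, imgt = list()), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain[!duplicated(x$atoms[, c("chain", "resno")])])
  cat("<structure_model> ", nrow(x$atoms), " atoms; chains: ",
      paste(sprintf("%s (%d res)", names(ch), as.integer(ch)),
            collapse = ", "), "\n", sep = "")
  if (length(x$imgt) > 0) {
    cat("  IMGT-annotated chains: ", paste(names(x$imgt), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' PDB files are read through bio3d; mmCIF files through a minimal
#' `atom_site` reader.  In both cases the first model is kept, altloc `""`
#' or `"A"` preferred, and hydrogens discarded.
#'
#' @param path file path (`.pdb`, `.ent`, `.cif`, `.mmcif`).
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else
    read_mmcif_atoms(path)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  structure_model(atoms)
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  elem[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  data.frame(chain = as.character(at$chain), resno = at$resno,
             resname = at$resid, atom = at$elety,
             element = toupper(trimws(elem)),
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

# Minimal mmCIF reader: parses the first atom_site loop.  No installed R
# package reads mmCIF, hence the hand-written reader; it supports the
# standard whitespace-separated rows with quoted fields.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^_atom_site\\.", lines)
  if (length(starts) == 0) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[starts]))
  body_start <- max(starts) + 1L
  rows <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    rows <- c(rows, ln)
  }
  tok <- lapply(rows, function(ln) {
    scan(text = ln, what = character(), quiet = TRUE)
  })
  bad <- lengths(tok) != length(fields)
  if (any(bad)) stop("malformed atom_site row(s) in ", path)
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  col <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else stop("atom_site lacks field ", nm)
  }
  model <- if ("pdbx_PDB_model_num" %in% fields)
    col("pdbx_PDB_model_num") else "1"
  alt <- if ("label_alt_id" %in% fields) col("label_alt_id") else "."
  keep <- model == model[1] & alt %in% c(".", "?", "A")
  data.frame(
    chain = col("auth_asym_id", "label_asym_id")[keep],
    resno = as.integer(col("auth_seq_id", "label_seq_id")[keep]),
    resname = col("label_comp_id", "auth_comp_id")[keep],
    atom = gsub('"', "", col("label_atom_id", "auth_atom_id")[keep]),
    element = toupper(col("type_symbol")[keep]),
    x = as.numeric(col("Cartn_x")[keep]),
    y = as.numeric(col("Cartn_y")[keep]),
    z = as.numeric(col("Cartn_z")[keep]),
    stringsAsFactors = FALSE
  )
}

#' Write a structure model as PDB
#'
#' Plain fixed-width ATOM records, one chain per segment, suitable for
#' inspection of synthetic fixtures and for round-tripping through
#' [read_structure()].
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_structure_pdb <- function(model, path) {
  at <- model$atoms
  name <- ifelse(nchar(at$atom) < 4, sprintf(" %-3s", at$atom),
                 sprintf("%-4s", at$atom))
  rec <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name, at$resname, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, at$element
  )
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Extract a chain's one-letter sequence from coordinates
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @return list with `sequence` (string) and `resno` (integer vector, one
#'   per residue in order).
#' @export
chain_sequence <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain ", chain, " absent from model")
  res <- at[!duplicated(at$resno), c("resno", "resname")]
  res <- res[order(res$resno), ]
  aa1 <- bio3d::aa321(res$resname)
  keep <- aa1 != "X"
  list(sequence = paste(aa1[keep], collapse = ""),
       resno = res$resno[keep])
}

#' Annotate a structure chain with IMGT positions
#'
#' Extracts the chain's sequence from the coordinates, numbers it against a
#' reference with [assign_imgt_numbering()] and stores the residue-number
#' to IMGT-label map on the model.  Unmodeled or inserted residues simply
#' remain unlabeled.
#'
#' Chains longer than a single C-domain (e.g. a full Fc chain carrying
#' CH2 and CH3) are handled by first locating the reference domain within
#' the chain by global-local alignment and numbering that window; residues
#' outside the window stay unlabeled.
#'
#' @param model a [structure_model()].
#' @param numbered reference [numbered_domain()] to number against.
#' @param chain chain identifier.
#' @param ... passed to [assign_imgt_numbering()].
#' @return the annotated [structure_model()].
#' @export
annotate_structure <- function(model, numbered, chain, ...) {
  cs <- chain_sequence(model, chain)
  seq <- cs$sequence
  win <- c(1L, nchar(seq))
  if (nchar(seq) > 140L) {
    loc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(numbered$sequence), Biostrings::AAString(seq),
      type = "global-local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    win <- c(Biostrings::start(Biostrings::subject(loc)),
             Biostrings::end(Biostrings::subject(loc)))
    seq <- substr(seq, win[1], win[2])
  }
  dom <- assign_imgt_numbering(seq, numbered, ...)
  map <- data.frame(resno = cs$resno[seq(win[1], win[2])],
                    imgt = dom$labels, stringsAsFactors = FALSE)
  model$imgt[[chain]] <- map[!is.na(map$imgt), , drop = FALSE]
  model
}

# IMGT label for given residues of an annotated chain (NA if unannotated).
imgt_of <- function(model, chain, resno) {
  map <- model$imgt[[chain]]
  if (is.null(map)) return(rep(NA_character_, length(resno)))
  map$imgt[match(resno, map$resno)]
}

# Residue number carrying a given IMGT label on an annotated chain.
resno_of <- function(model, chain, position) {
  map <- model$imgt[[chain]]
  if (is.null(map)) stop("chain ", chain, " is not IMGT-annotated")
  map$resno[match(as.character(position), map$imgt)]
}
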