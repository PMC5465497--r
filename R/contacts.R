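#' Interdomain contact criteria
#'
#' Distance criteria for the two contact kinds the interface diagrams
#' report, in the style of residue-interaction servers: a hydrophobic
#' contact is any pair of side-chain carbon atoms of apolar residues within
#' `hydrophobic_cutoff`; an ionic contact is any side-chain N/O atom of a
#' basic residue within `ionic_cutoff` of a side-chain oxygen of an acidic
#' residue.
#'
#' @param hydrophobic_cutoff,ionic_cutoff distances in Angstrom.
#' @param hydrophobic_residues three-letter codes treated as apolar.
#' @return list of criteria for [compute_contacts()].
#' @export
contact_criteria <- function(hydrophobic_cutoff = 5.0, ionic_cutoff = 6.0,
                             hydrophobic_residues = c("ALA", "VAL", "LEU",
                                                      "ILE", "MET", "PHE",
                                                      "TRP", "PRO",
                                                      "TYR")) {
  list(hydrophobic_cutoff = hydrophobic_cutoff,
       ionic_cutoff = ionic_cutoff,
       hydrophobic_residues = hydrophobic_residues,
       basic_residues = c("LYS", "ARG", "HIS"),
       acidic_residues = c("ASP", "GLU"),
       backbone_atoms = c("N", "CA", "C", "O", "OXT"))
}

side_chain_atoms <- function(atoms, criteria) {
  !(atoms$atom %in% criteria$backbone_atoms)
}

#' Interdomain contact map
#'
#' Finds all residue pairs across two chains that meet the hydrophobic or
#' ionic criteria, reporting for each pair the minimal qualifying
#' atom-atom distance.  The result is invariant to the order of the two
#' chain arguments (pairs are canonicalized so `chain_i` is the
#' alphabetically first chain).  A chain without qualifying atoms yields an
#' empty map, not an error.
#'
#' @param model a [structure_model()].
#' @param chains length-2 character vector of chain identifiers.
#' @param criteria see [contact_criteria()].
#' @return a data.frame of class `contact_map` with columns `kind`,
#'   `chain_i`, `resno_i`, `resname_i`, `imgt_i`, `chain_j`, `resno_j`,
#'   `resname_j`, `imgt_j`, `min_distance`; criteria kept in
#'   `attr(x, "criteria")`.
#' @export
compute_contacts <- function(model, chains, criteria = contact_criteria()) {
  stopifnot(length(chains) == 2L)
  for (ch in chains) {
    if (!ch %in% model$atoms$chain) stop("chain ", ch, " absent from model")
  }
  chains <- sort(as.character(chains))
  at <- model$atoms
  sc <- side_chain_atoms(at, criteria)

  sel <- list(
    hydrophobic = list(
      i = sc & at$element == "C" &
        at$resname %in% criteria$hydrophobic_residues,
      j = sc & at$element == "C" &
        at$resname %in% criteria$hydrophobic_residues,
      cutoff = criteria$hydrophobic_cutoff, symmetric = TRUE),
    ionic = list(
      i = sc & at$element %in% c("N", "O") &
        at$resname %in% criteria$basic_residues,
      j = sc & at$element == "O" &
        at$resname %in% criteria$acidic_residues,
      cutoff = criteria$ionic_cutoff, symmetric = FALSE)
  )

  out <- list()
  for (kind in names(sel)) {
    s <- sel[[kind]]
    combos <- list(c(1L, 2L))
    if (!s$symmetric) combos <- list(c(1L, 2L), c(2L, 1L))
    for (cb in combos) {
      ai <- at[s$i & at$chain == chains[cb[1]], , drop = FALSE]
      aj <- at[s$j & at$chain == chains[cb[2]], , drop = FALSE]
      if (nrow(ai) == 0 || nrow(aj) == 0) next
      d2 <- outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
        outer(ai$z, aj$z, "-")^2
      hit <- which(d2 <= s$cutoff^2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      df <- data.frame(
        kind = kind,
        chain_i = ai$chain[hit[, 1]], resno_i = ai$resno[hit[, 1]],
        resname_i = ai$resname[hit[, 1]],
        chain_j = aj$chain[hit[, 2]], resno_j = aj$resno[hit[, 2]],
        resname_j = aj$resname[hit[, 2]],
        min_distance = sqrt(d2[hit]),
        stringsAsFactors = FALSE
      )
      # canonical orientation: residue on the first chain is always res_i
      if (cb[1] == 2L) {
        df <- data.frame(kind = df$kind, chain_i = df$chain_j,
                         resno_i = df$resno_j, resname_i = df$resname_j,
                         chain_j = df$chain_i, resno_j = df$resno_i,
                         resname_j = df$resname_i,
                         min_distance = df$min_distance,
                         stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- df
    }
  }
  if (length(out) == 0) {
    res <- data.frame(kind = character(0), chain_i = character(0),
                      resno_i = integer(0), resname_i = character(0),
                      chain_j = character(0), resno_j = integer(0),
                      resname_j = character(0),
                      min_distance = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    key <- paste(res$kind, res$resno_i, res$resno_j)
    res <- res[order(key, res$min_distance), , drop = FALSE]
    res <- res[!duplicated(paste(res$kind, res$resno_i, res$resno_j)), ,
               drop = FALSE]
    res <- res[order(res$kind, res$resno_i, res$resno_j), , drop = FALSE]
  }
  res$imgt_i <- imgt_of(model, chains[1], res$resno_i)
  res$imgt_j <- imgt_of(model, chains[2], res$resno_j)
  res <- res[, c("kind", "chain_i", "resno_i", "resname_i", "imgt_i",
                 "chain_j", "resno_j", "resname_j", "imgt_j",
                 "min_distance")]
  rownames(res) <- NULL
  attr(res, "criteria") <- criteria
  class(res) <- c("contact_map", class(res))
  res
}

#' Text diagram of an interface contact map
#'
#' Deterministic plain-text rendering of a contact map: contacts grouped
#' by kind, ordered by IMGT position (or residue number where
#' unannotated), each flagged `symmetric` when the reciprocal position
#' pair is also in contact (the hallmark of a homodimeric interface) or
#' `asymmetric` otherwise.
#'
#' @param map a contact map from [compute_contacts()].
#' @return character vector of report lines.
#' @export
render_interface_diagram <- function(map) {
  header <- sprintf("Interface contacts (%d)", nrow(map))
  if (nrow(map) == 0) return(c(header, "  (none)"))
  lab_i <- ifelse(is.na(map$imgt_i), as.character(map$resno_i), map$imgt_i)
  lab_j <- ifelse(is.na(map$imgt_j), as.character(map$resno_j), map$imgt_j)
  key_fwd <- paste(map$kind, lab_i, lab_j)
  key_rev <- paste(map$kind, lab_j, lab_i)
  sym <- ifelse(key_rev %in% key_fwd, "symmetric", "asymmetric")
  ord <- order(map$kind,
               suppressWarnings(imgt_key(lab_i)),
               suppressWarnings(imgt_key(lab_j)))
  lines <- header
  for (kind in unique(map$kind[ord])) {
    rows <- ord[map$kind[ord] == kind]
    lines <- c(lines, paste0(kind, ":"))
    lines <- c(lines, sprintf(
      "  %s %s %s -- %s %s %s  %.2f A  [%s]",
      map$chain_i[rows], map$resname_i[rows], lab_i[rows],
      map$chain_j[rows], map$resname_j[rows], lab_j[rows],
      map$min_distance[rows], sym[rows]))
  }
  lines
}

#' Export a contact map as TSV
#'
#' @param map a contact map from [compute_contacts()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_contacts_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
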