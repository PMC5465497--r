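#' Packaged C-domain reference set
#'
#' Loads the curated constant-domain references shipped with the package:
#' nine classes (IgG1/IgG3/IgA/IgD CH3, IgM CH4 and the TCR Ca/Cb/Cg/Cd
#' constant domains), each an amino-acid sequence with authoritative IMGT
#' C-DOMAIN numbering on a shared 103-position scaffold.
#'
#' The sequences are curated reconstructions, not verbatim database
#' exports: the IgG1 CH3 entry is the canonical human IGHG1 CH3 sequence,
#' and the remaining entries follow their germline gene flavour but are
#' curated at interface columns so that every wild-type letter implied by
#' the packaged interface-exchange designs holds.  That contract is
#' re-checked on every load (see [check_reference_consistency()]); a
#' mismatch is a packaging error and fails loudly.
#'
#' @param check run the consistency check (default `TRUE`).
#' @return named list of [numbered_domain()] objects keyed by domain class.
#' @examples
#' refs <- reference_set()
#' names(refs)
#' residue_at(refs[["TCR-Ca"]], "88")
#' @export
reference_set <- function(check = TRUE) {
  cached <- get0("references", envir = .igraft_cache)
  if (!is.null(cached)) return(cached)
  fasta <- system.file("extdata", "cdomain_references_synthetic.fasta",
                       package = "igraft", mustWork = TRUE)
  tsv <- system.file("extdata", "cdomain_numbering_synthetic.tsv",
                     package = "igraft", mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
  tab <- utils::read.delim(tsv, colClasses = "character")
  refs <- lapply(names(seqs), function(cl) {
    num <- tab[tab$domain_class == cl, ]
    num <- num[order(as.integer(num$residue_index)), ]
    dom <- numbered_domain(as.character(seqs[[cl]]), num$imgt_label, cl)
    if (!identical(strsplit(dom$sequence, "")[[1]], num$residue)) {
      stop("reference FASTA and numbering table disagree for ", cl)
    }
    dom
  })
  names(refs) <- names(seqs)
  if (check) check_reference_consistency(refs)
  assign("references", refs, envir = .igraft_cache)
  refs
}

.igraft_cache <- new.env(parent = emptyenv())

#' Domain classes that form homodimers
#'
#' The antibody constant-domain classes whose natural dimer is a homodimer;
#' only these are valid acceptors, and valid donors for half-interface
#' (mixed interface) grafting.  TCR constant domains are natural
#' heterodimers and serve as full-interface donors.
#'
#' @return character vector of class tags.
#' @export
homodimer_classes <- function() {
  c("IgG1-CH3", "IgG3-CH3", "IgA-CH3", "IgD-CH3", "IgM-CH4")
}

# One-letter Ig class abbreviations used by the mixed-interface naming
# convention (first letter = class donating position 88, second = class
# donating positions 85.1/86).
class_letter <- function(domain_class) {
  map <- c(`IgG1-CH3` = "G", `IgG3-CH3` = "G", `IgA-CH3` = "A",
           `IgD-CH3` = "D", `IgM-CH4` = "M")
  letter <- map[domain_class]
  if (anyNA(letter)) {
    stop("no class letter for ", domain_class[is.na(letter)])
  }
  unname(letter)
}

# Wild-type letters that the packaged designs imply.  Key sets, supporting
# positions and variant rules pin these residues; the references must agree
# or generated substitution lists would silently deviate from the designs
# they are documented to reproduce.
.design_wildtype <- list(
  `IgG1-CH3` = c(`3` = "Q", `5` = "Y", `7` = "L", `13` = "E", `16` = "K",
                 `20` = "S", `22` = "T", `24` = "L", `26` = "K", `27` = "G",
                 `79` = "K", `81` = "T", `84` = "V", `84.2` = "D",
                 `84.4` = "D", `85.1` = "F", `86` = "Y", `88` = "K",
                 `90` = "T", `115` = "H", `116` = "Y"),
  `TCR-Ca` = c(`3` = "Q", `5` = "Y", `7` = "L", `20` = "K", `22` = "V",
               `26` = "T", `27` = "G", `79` = "Y", `81` = "T", `84` = "V",
               `84.2` = "D", `85.1` = "S", `86` = "V", `88` = "W",
               `90` = "N"),
  `TCR-Cb` = c(`3` = "E", `5` = "A", `7` = "F", `20` = "T", `22` = "V",
               `26` = "T", `27` = "G", `79` = "K", `81` = "D", `84` = "L",
               `84.2` = "E", `84.4` = "D", `85.1` = "C", `86` = "S",
               `88` = "R", `90` = "R"),
  `IgA-CH3` = c(`3` = "E", `26` = "R", `81` = "W", `90` = "R"),
  `IgM-CH4` = c(`115` = "R", `116` = "V"),
  `IgG3-CH3` = c(`115` = "R", `116` = "F")
)

#' Check packaged references against the design contract
#'
#' Asserts that every wild-type letter implied by the packaged
#' interface-exchange designs (printed substitution lists, variant rules,
#' Protein A engineering) holds in the packaged references, that all
#' fifteen interface positions are present in every reference, and that the
#' IgG3 CH3 entry agrees with IgG1 CH3 across the interface catalog (the
#' CH3 designs apply to either isotype context).
#'
#' @param refs reference list as returned by [reference_set()].
#' @return invisibly `TRUE`; errors on any violation.
#' @export
check_reference_consistency <- function(refs) {
  needed <- c("IgG1-CH3", "IgG3-CH3", "IgA-CH3", "IgD-CH3", "IgM-CH4",
              "TCR-Ca", "TCR-Cb", "TCR-Cg", "TCR-Cd")
  absent <- setdiff(needed, names(refs))
  if (length(absent) > 0) {
    stop("reference set is missing class(es): ",
         paste(absent, collapse = ", "))
  }
  for (cl in needed) {
    missing <- setdiff(interface_positions(), domain_positions(refs[[cl]]))
    if (length(missing) > 0) {
      stop(cl, " reference lacks interface position(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (cl in names(.design_wildtype)) {
    want <- .design_wildtype[[cl]]
    got <- residue_at(refs[[cl]], names(want), required = TRUE)
    bad <- got != want
    if (any(bad)) {
      stop(cl, " reference breaks the design contract at ",
           paste(sprintf("%s (expected %s, found %s)", names(want)[bad],
                         want[bad], got[bad]), collapse = "; "))
    }
  }
  ifc <- interface_positions()
  g1 <- residue_at(refs[["IgG1-CH3"]], ifc, required = TRUE)
  g3 <- residue_at(refs[["IgG3-CH3"]], ifc, required = TRUE)
  if (any(g1 != g3)) {
    stop("IgG3-CH3 disagrees with IgG1-CH3 at interface position(s): ",
         paste(ifc[g1 != g3], collapse = ", "))
  }
  invisible(TRUE)
}
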