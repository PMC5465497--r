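#' Constant-domain sequence with IMGT numbering
#'
#' A `numbered_domain` couples an amino-acid sequence with a per-residue IMGT
#' C-DOMAIN position label and a domain class tag.  Residues without a
#' catalog label (insertions relative to the reference used for numbering)
#' carry `NA` and are listed in the `insertions` attribute.
#'
#' @param sequence amino-acid string (one-letter code).
#' @param labels character vector of IMGT labels, one per residue; `NA`
#'   marks an unlabeled insertion.
#' @param domain_class class tag, e.g. `"IgG1-CH3"`, `"TCR-Ca"` or
#'   `"custom"`.
#' @return an object of class `numbered_domain`.
#' @export
numbered_domain <- function(sequence, labels, domain_class = "custom") {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L)
  n <- nchar(sequence)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("numbering length (", length(labels),
         ") does not match sequence length (", n, ")")
  }
  lab <- labels[!is.na(labels)]
  if (anyDuplicated(lab)) {
    stop("duplicated IMGT position(s): ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (is.unsorted(imgt_key(lab), strictly = TRUE)) {
    stop("IMGT labels are not strictly increasing along the chain")
  }
  structure(
    list(sequence = sequence, labels = labels, domain_class = domain_class),
    class = "numbered_domain"
  )
}

#' @export
print.numbered_domain <- function(x, ...) {
  n <- nchar(x$sequence)
  ins <- sum(is.na(x$labels))
  cat("<numbered_domain> ", x$domain_class, ": ", n, " residues",
      if (ins > 0) paste0(" (", ins, " unlabeled insertion(s))"), "\n",
      sep = "")
  cat(" ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.numbered_domain <- function(x, ...) {
  data.frame(residue_index = seq_len(nchar(x$sequence)),
             imgt_label = x$labels,
             residue = strsplit(x$sequence, "")[[1]],
             stringsAsFactors = FALSE)
}

#' Residue lookup by IMGT position
#'
#' @param domain a [numbered_domain()].
#' @param position IMGT label(s), e.g. `"88"` or `"85.1"`.
#' @param required error (rather than return `NA`) when a position is
#'   absent.
#' @return character vector of one-letter residues (`NA` where absent and
#'   `required = FALSE`).
#' @export
residue_at <- function(domain, position, required = FALSE) {
  idx <- match(as.character(position), domain$labels)
  if (required && anyNA(idx)) {
    stop("position(s) missing from ", domain$domain_class, ": ",
         paste(position[is.na(idx)], collapse = ", "))
  }
  res <- rep(NA_character_, length(idx))
  res[!is.na(idx)] <- substring(domain$sequence, idx[!is.na(idx)],
                                idx[!is.na(idx)])
  res
}

#' IMGT positions present in a domain
#'
#' @param domain a [numbered_domain()].
#' @return character vector of labels in chain order (insertions omitted).
#' @export
domain_positions <- function(domain) {
  domain$labels[!is.na(domain$labels)]
}

# "CH3"/"CH4"/... suffix of a class tag such as "IgG1-CH3".
domain_type <- function(domain_class) {
  sub("^.*-", "", domain_class)
}

#' Assign IMGT numbering to a constant-domain sequence
#'
#' Numbers a user-supplied sequence by global alignment to a numbered
#' reference and transfer of labels across aligned columns.  Residues of
#' `seq` aligned to reference gaps receive no label and are flagged as
#' insertions; reference positions aligned to gaps in `seq` are absent from
#' the result.  Any of the fifteen catalog interface positions landing on a
#' gap is an error, because a domain lacking interface positions cannot take
#' part in interface exchange.
#'
#' @param seq amino-acid string, 80 to 140 residues.
#' @param reference a fully numbered [numbered_domain()], typically from
#'   [reference_set()].
#' @param min_identity minimum fraction of identical aligned positions below
#'   which the sequence is rejected as not a recognizable C-domain.
#' @param domain_class class tag for the result; defaults to the
#'   reference's.
#' @return a [numbered_domain()]; unlabeled insertions (if any) are listed
#'   in `attr(x, "insertions")` as residue indices.
#' @examples
#' refs <- reference_set()
#' dom <- assign_imgt_numbering(refs[["IgG1-CH3"]]$sequence,
#'                              refs[["IgG1-CH3"]])
#' residue_at(dom, "88")
#' @export
assign_imgt_numbering <- function(seq, reference, min_identity = 0.30,
                                  domain_class = NULL) {
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)))
  stopifnot(inherits(reference, "numbered_domain"))
  if (nchar(seq) < 80L || nchar(seq) > 140L) {
    stop("sequence length ", nchar(seq),
         " outside the supported C-domain range [80, 140]")
  }
  if (anyNA(reference$labels)) {
    stop("reference numbering is incomplete")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(reference$sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pat != "-" & sub_ != "-"
  identity <- sum(pat[both] == sub_[both]) / max(1L, sum(both))
  if (identity < min_identity) {
    stop(sprintf(paste0("not a recognizable C-domain: alignment identity ",
                        "%.2f below floor %.2f against %s"),
                 identity, min_identity, reference$domain_class))
  }
  labels <- rep(NA_character_, nchar(seq))
  pi <- 0L; si <- 0L
  missing_ref <- character(0)
  for (k in seq_along(pat)) {
    p_gap <- pat[k] == "-"; s_gap <- sub_[k] == "-"
    if (!p_gap) pi <- pi + 1L
    if (!s_gap) si <- si + 1L
    if (!p_gap && !s_gap) {
      labels[pi] <- reference$labels[si]
    } else if (p_gap && !s_gap) {
      missing_ref <- c(missing_ref, reference$labels[si])
    }
  }
  lost <- intersect(interface_positions(), missing_ref)
  if (length(lost) > 0) {
    stop("missing interface position(s) in sequence: ",
         paste(imgt_sort(lost), collapse = ", "))
  }
  out <- numbered_domain(seq, labels,
                         domain_class %||% reference$domain_class)
  attr(out, "insertions") <- which(is.na(labels))
  attr(out, "identity") <- identity
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
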