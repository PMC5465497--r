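#' Point-substitution lists in IMGT coordinates
#'
#' A substitution list is a data.frame with character columns `wt`,
#' `position` and `mut`, one row per substitution, rendered in the compact
#' notation `S20K` / `F85.1A` (wild-type letter, IMGT position, mutant
#' letter).
#'
#' @param wt,mut one-letter amino-acid codes.
#' @param position IMGT position label(s).
#' @return `substitution_list()` returns the validated data.frame;
#'   `format_substitutions()` a character vector in compact notation;
#'   `parse_substitutions()` the data.frame parsed back from compact
#'   notation.
#' @examples
#' parse_substitutions(c("S20K", "F85.1A"))
#' @export
substitution_list <- function(wt = character(0), position = character(0),
                              mut = character(0)) {
  df <- data.frame(wt = toupper(as.character(wt)),
                   position = as.character(position),
                   mut = toupper(as.character(mut)),
                   stringsAsFactors = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (nrow(df) > 0) {
    imgt_parse(df$position)  # validates labels
    if (!all(df$wt %in% aa) || !all(df$mut %in% aa)) {
      stop("substitutions must use standard one-letter amino-acid codes")
    }
    if (any(df$wt == df$mut)) {
      stop("substitution with identical wild-type and mutant residue: ",
           paste(format_substitutions(df[df$wt == df$mut, ]),
                 collapse = ", "))
    }
    if (anyDuplicated(df$position)) {
      stop("more than one substitution at position(s): ",
           paste(unique(df$position[duplicated(df$position)]),
                 collapse = ", "))
    }
    df <- df[order(imgt_key(df$position)), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname substitution_list
#' @param subs a substitution list data.frame.
#' @export
format_substitutions <- function(subs) {
  if (nrow(subs) == 0) return(character(0))
  paste0(subs$wt, subs$position, subs$mut)
}

#' @rdname substitution_list
#' @param x character vector in compact notation, e.g. `"F85.1A"`.
#' @export
parse_substitutions <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+(?:\\.[0-9]+)?)([A-Za-z])$",
                             as.character(x)))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed substitution notation: ",
         paste(x[bad], collapse = ", "))
  }
  parts <- do.call(rbind, m)
  substitution_list(parts[, 2], parts[, 3], parts[, 4])
}

#' Apply a substitution list to a numbered domain
#'
#' Each substitution's wild-type letter must match the current residue at
#' its position; the mutant letter replaces it.  Positions outside the
#' domain's numbering are an error.
#'
#' @param domain a [numbered_domain()].
#' @param subs substitution list (data.frame or compact-notation character
#'   vector).
#' @return the mutated [numbered_domain()].
#' @export
apply_substitutions <- function(domain, subs) {
  if (is.character(subs)) subs <- parse_substitutions(subs)
  if (nrow(subs) == 0) return(domain)
  chars <- strsplit(domain$sequence, "")[[1]]
  idx <- match(subs$position, domain$labels)
  if (anyNA(idx)) {
    stop("position(s) missing from ", domain$domain_class, ": ",
         paste(subs$position[is.na(idx)], collapse = ", "))
  }
  mism <- chars[idx] != subs$wt
  if (any(mism)) {
    stop("wild-type mismatch in ", domain$domain_class, ": ",
         paste(sprintf("%s (expected %s, found %s)",
                       format_substitutions(subs)[mism],
                       subs$wt[mism], chars[idx][mism]), collapse = "; "))
  }
  chars[idx] <- subs$mut
  out <- numbered_domain(paste(chars, collapse = ""), domain$labels,
                         domain$domain_class)
  attributes(out) <- c(attributes(out),
                       attributes(domain)[setdiff(names(attributes(domain)),
                                                  names(attributes(out)))])
  out
}
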