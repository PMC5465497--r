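#' Plain-text design report
#'
#' Deterministic report bundle for an engineered pair: design provenance,
#' per-chain substitution tables in compact notation, the applied-rules
#' log and, optionally, interface diagrams of supplied contact maps.
#'
#' @param pair an [engineered_pair].
#' @param maps optional named list of contact maps (see
#'   [compute_contacts()]) appended as diagrams.
#' @return character vector of report lines.
#' @examples
#' cat(design_report(beat_min()), sep = "\n")
#' @export
design_report <- function(pair, maps = NULL) {
  stopifnot(inherits(pair, "engineered_pair"))
  lines <- c(
    paste0("Design: ", pair$design_name),
    paste0("Acceptor: ", pair$acceptor_class),
    paste0("Donors:   ", pair$donor_a_class, " (chain A) / ",
           pair$donor_b_class, " (chain B)"),
    ""
  )
  for (ch in c("a", "b")) {
    subs <- pair[[paste0("subs_", ch)]]
    lines <- c(lines, sprintf("Chain %s substitutions (%d):", toupper(ch),
                              nrow(subs)))
    if (nrow(subs) == 0) {
      lines <- c(lines, "  (none)")
    } else {
      lines <- c(lines,
                 paste0("  ", paste(format_substitutions(subs),
                                    collapse = ", ")),
                 sprintf("  %-4s %-8s %-4s", "wt", "position", "mut"),
                 sprintf("  %-4s %-8s %-4s", subs$wt, subs$position,
                         subs$mut))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Rules applied:",
             if (length(pair$rules_applied) == 0) "  (none)" else
               paste0("  - ", pair$rules_applied))
  for (nm in names(maps)) {
    lines <- c(lines, "", paste0("Contact map: ", nm),
               render_interface_diagram(maps[[nm]]))
  }
  lines
}

#' Export an engineered pair's substitution lists as TSV
#'
#' Columns `chain`, `wt`, `imgt_position`, `mut`, plus the compact
#' notation.
#'
#' @param pair an [engineered_pair].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_substitutions_tsv <- function(pair, path) {
  rows <- do.call(rbind, lapply(c("a", "b"), function(ch) {
    subs <- pair[[paste0("subs_", ch)]]
    if (nrow(subs) == 0) return(NULL)
    data.frame(chain = toupper(ch), wt = subs$wt,
               imgt_position = subs$position, mut = subs$mut,
               compact = format_substitutions(subs),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(chain = character(0), wt = character(0),
                       imgt_position = character(0), mut = character(0),
                       compact = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export engineered chains as FASTA
#'
#' Headers carry the design name, chain and substitution count.
#'
#' @param pair an [engineered_pair].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pair_fasta <- function(pair, path) {
  seqs <- Biostrings::AAStringSet(c(pair$chain_a$sequence,
                                    pair$chain_b$sequence))
  names(seqs) <- sprintf("%s|chain_%s|%s|%d_substitutions",
                         gsub("[[:space:]]", "_", pair$design_name),
                         c("A", "B"),
                         c(pair$chain_a$domain_class,
                           pair$chain_b$domain_class),
                         c(nrow(pair$subs_a), nrow(pair$subs_b)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
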