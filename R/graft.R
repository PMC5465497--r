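#' Engineered heterodimeric domain pairs
#'
#' An `engineered_pair` holds the two engineered chains of a designed
#' heterodimer, the per-chain substitution lists relative to the acceptor,
#' the design name and an audit log of the rules applied (skip-identical,
#' cysteine avoidance, named variants).  Pairs are produced by
#' [full_interface_graft()], [half_interface_graft()] and the packaged
#' design constructors ([beat_design()] and friends).
#'
#' @name engineered_pair
NULL

new_engineered_pair <- function(acceptor, chain_a, chain_b, subs_a, subs_b,
                                design_name, donor_a_class, donor_b_class,
                                rules_applied = character(0)) {
  structure(
    list(acceptor = acceptor, chain_a = chain_a, chain_b = chain_b,
         subs_a = subs_a, subs_b = subs_b, design_name = design_name,
         acceptor_class = acceptor$domain_class,
         donor_a_class = donor_a_class, donor_b_class = donor_b_class,
         rules_applied = rules_applied),
    class = "engineered_pair"
  )
}

#' @export
print.engineered_pair <- function(x, ...) {
  cat("<engineered_pair> ", x$design_name, "\n", sep = "")
  cat("  acceptor: ", x$acceptor_class, "; donors: ", x$donor_a_class,
      " / ", x$donor_b_class, "\n", sep = "")
  for (ch in c("a", "b")) {
    subs <- x[[paste0("subs_", ch)]]
    cat(sprintf("  chain %s: %d substitution(s)", toupper(ch), nrow(subs)))
    if (nrow(subs) > 0) {
      cat(": ", paste(format_substitutions(subs), collapse = ", "),
          sep = "")
    }
    cat("\n")
  }
  if (length(x$rules_applied) > 0) {
    cat("  rules:\n")
    cat(paste0("    - ", x$rules_applied, "\n"), sep = "")
  }
  invisible(x)
}

# Grafts donor residues onto the acceptor at the requested positions.
# Skip-identical: a substitution is emitted only where the (rule-adjusted)
# donor residue differs from the acceptor.  Cys avoidance: a donor cysteine
# at a grafted position becomes alanine, preventing unpaired/mispaired
# disulfides, and is logged.
graft_chain <- function(acceptor, donor, positions, chain_label) {
  for (dom in list(acceptor, donor)) {
    missing <- setdiff(positions, domain_positions(dom))
    if (length(missing) > 0) {
      stop("domain ", dom$domain_class, " lacks requested position(s): ",
           paste(imgt_sort(missing), collapse = ", "))
    }
  }
  positions <- imgt_sort(positions)
  wt <- residue_at(acceptor, positions, required = TRUE)
  res <- residue_at(donor, positions, required = TRUE)
  log <- character(0)
  cys <- res == "C"
  if (any(cys)) {
    res[cys] <- "A"
    log <- sprintf("cys-avoidance [chain %s]: donor %s Cys at %s -> Ala",
                   chain_label, donor$domain_class, positions[cys])
  }
  keep <- res != wt
  subs <- substitution_list(wt[keep], positions[keep], res[keep])
  list(domain = apply_substitutions(acceptor, subs), subs = subs,
       log = log)
}

#' Full-interface graft from a heterodimeric donor pair
#'
#' Exchanges the interface of an acceptor homodimer with the complete
#' interface of a natural heterodimer: chain A receives `donor_a`'s residue
#' at every requested position, chain B receives `donor_b`'s.  A
#' substitution is emitted only where donor and acceptor differ
#' (skip-identical), and a donor cysteine at a grafted position is imported
#' as alanine (cys-avoidance, logged).
#'
#' @param acceptor a [numbered_domain()]: the homodimer unit to engineer.
#' @param donor_a,donor_b the two [numbered_domain()]s of the donor
#'   heterodimer.
#' @param positions_a,positions_b IMGT positions grafted on each chain;
#'   default the full 15-position interface catalog.  Must be subsets of
#'   [interface_positions()].
#' @param design_name optional design label.
#' @return an [engineered_pair].
#' @examples
#' refs <- reference_set()
#' beat <- full_interface_graft(refs[["IgG1-CH3"]], refs[["TCR-Ca"]],
#'                              refs[["TCR-Cb"]], design_name = "BEAT")
#' format_substitutions(beat$subs_a)
#' @export
full_interface_graft <- function(acceptor, donor_a, donor_b,
                                 positions_a = interface_positions(),
                                 positions_b = interface_positions(),
                                 design_name = NULL) {
  for (p in list(positions_a, positions_b)) {
    extra <- setdiff(p, interface_positions())
    if (length(extra) > 0) {
      stop("position(s) outside the interface catalog: ",
           paste(extra, collapse = ", "))
    }
  }
  a <- graft_chain(acceptor, donor_a, positions_a, "A")
  b <- graft_chain(acceptor, donor_b, positions_b, "B")
  name <- design_name %||%
    sprintf("%s interface graft of %s/%s", acceptor$domain_class,
            donor_a$domain_class, donor_b$domain_class)
  new_engineered_pair(
    acceptor, a$domain, b$domain, a$subs, b$subs, name,
    donor_a$domain_class, donor_b$domain_class,
    c("skip-identical", a$log, b$log)
  )
}

#' Half-interface graft between two homodimers (mixed interface design)
#'
#' Breaks the symmetry of an acceptor homodimer by exchanging half of its
#' interface with the equivalent half-interface of a donor homodimer.
#' Because a homodimeric interface is symmetric, the four key sets of a
#' heterodimeric interface collapse to two: chain 1 takes the donor's
#' residues at positions 88 and 20 (supported by 79, 81 and 90) and chain 2
#' at positions 26, 85.1 and 86 (supported by 3, 5, 84 and 84.2).
#' Skip-identical and cys-avoidance apply as in [full_interface_graft()].
#'
#' The design name follows the mixed-interface (MI) convention: each chain
#' is a two-letter abbreviation, first letter the Ig class of its position
#' 88, second the class of its positions 85.1/86, e.g. grafting half the
#' IgD CH3 interface onto IgG1 CH3 gives `"MI (CH3) DG/GD"`.
#'
#' @param acceptor,donor [numbered_domain()]s of homodimer-forming classes
#'   (see [homodimer_classes()]).
#' @return an [engineered_pair] (chain 1 as `chain_a`, chain 2 as
#'   `chain_b`).
#' @examples
#' refs <- reference_set()
#' mi <- half_interface_graft(refs[["IgG1-CH3"]], refs[["IgD-CH3"]])
#' mi$design_name
#' @export
half_interface_graft <- function(acceptor, donor) {
  for (dom in list(acceptor, donor)) {
    if (!dom$domain_class %in% homodimer_classes()) {
      stop(dom$domain_class, " is not a homodimer-forming class; ",
           "half-interface mixing requires two homodimers")
    }
  }
  cat_ <- interface_catalog()
  a <- graft_chain(acceptor, donor, cat_$half_side_1, "1")
  b <- graft_chain(acceptor, donor, cat_$half_side_2, "2")
  da <- class_letter(donor$domain_class)
  ac <- class_letter(acceptor$domain_class)
  name <- sprintf("MI (%s) %s%s/%s%s", domain_type(acceptor$domain_class),
                  da, ac, ac, da)
  new_engineered_pair(
    acceptor, a$domain, b$domain, a$subs, b$subs, name,
    donor$domain_class, donor$domain_class,
    c("skip-identical", "half-interface partition", a$log, b$log)
  )
}

#' Packaged heterodimer designs
#'
#' Convenience constructors for the designs the package documents:
#' * `beat_design()` - the TCR Ca/Cb interface grafted onto IgG1 CH3 over
#'   the full 15-position catalog (chain A based on TCR Ca, chain B on TCR
#'   Cb, whose natural interface cysteine at 85.1 is imported as alanine).
#' * `beat_min()` - the reduced-substitution redesign: the same graft
#'   restricted to positions 20, 22, 26, 79, 88 and 90 on chain A and to
#'   85.1 and 86 on chain B.
#' * `beat_gd()` - the TCR Cg/Cd interface grafted onto IgG1 CH3 over the
#'   same position set as `beat_design()`.
#' * `beat_ch4()` - the TCR Ca/Cb interface grafted onto the IgM CH4
#'   homodimer.
#'
#' @param refs reference list, defaults to [reference_set()].
#' @return an [engineered_pair].
#' @examples
#' format_substitutions(beat_min()$subs_a)
#' @export
beat_design <- function(refs = reference_set()) {
  full_interface_graft(refs[["IgG1-CH3"]], refs[["TCR-Ca"]],
                       refs[["TCR-Cb"]], design_name = "BEAT")
}

#' @rdname beat_design
#' @export
beat_min <- function(refs = reference_set()) {
  full_interface_graft(refs[["IgG1-CH3"]], refs[["TCR-Ca"]],
                       refs[["TCR-Cb"]],
                       positions_a = c("20", "22", "26", "79", "88", "90"),
                       positions_b = c("85.1", "86"),
                       design_name = "BEAT min")
}

#' @rdname beat_design
#' @export
beat_gd <- function(refs = reference_set()) {
  full_interface_graft(refs[["IgG1-CH3"]], refs[["TCR-Cg"]],
                       refs[["TCR-Cd"]], design_name = "BEAT G/D")
}

#' @rdname beat_design
#' @export
beat_ch4 <- function(refs = reference_set()) {
  full_interface_graft(refs[["IgM-CH4"]], refs[["TCR-Ca"]],
                       refs[["TCR-Cb"]], design_name = "BEAT CH4")
}

#' Named variant rules
#'
#' The closed registry of named single-position variants applied on top of
#' a designed pair:
#' * `Q3A` (chain A): alanine at position 3, relieving steric hindrance of
#'   the glutamine side chain and improving heterodimerization.
#' * `R90T` (chain B): back-mutation undoing `T90R`, removing the
#'   Arg90-Glu84.2/Asp84.4 contacts that stabilize the chain-B homodimer.
#' * `D84.4Q` (chain B): the alternative homodimer-destabilizing change at
#'   the same contact network.
#' * `W81T` (chain A): back-mutation probing the hydrophobic role of a
#'   donor tryptophan at position 81 in mixed-interface designs.
#'
#' @return data.frame describing the registry.
#' @export
variant_registry <- function() {
  data.frame(
    variant = c("Q3A", "R90T", "D84.4Q", "W81T"),
    chain = c("A", "B", "B", "A"),
    wt = c("Q", "R", "D", "W"),
    position = c("3", "90", "84.4", "81"),
    mut = c("A", "T", "Q", "T"),
    stringsAsFactors = FALSE
  )
}

#' Apply a named variant to an engineered pair
#'
#' The target chain's residue at the variant position must match the rule's
#' expected wild-type, otherwise the variant is inapplicable and an error
#' reports the observed residue.  The substitution list is updated
#' consistently: undoing an earlier substitution removes its entry, a new
#' change appends one, and re-mutating an already-substituted position
#' rewrites its mutant letter.
#'
#' @param pair an [engineered_pair].
#' @param variant registry name, see [variant_registry()].
#' @param chain `"A"` or `"B"`; defaults to the registry's chain.
#' @return the modified [engineered_pair].
#' @examples
#' pair <- apply_variant(beat_design(), "D84.4Q")
#' format_substitutions(pair$subs_b)
#' @export
apply_variant <- function(pair, variant, chain = NULL) {
  stopifnot(inherits(pair, "engineered_pair"))
  reg <- variant_registry()
  row <- reg[reg$variant == variant, ]
  if (nrow(row) != 1L) {
    stop("unknown variant '", variant, "'; registry: ",
         paste(reg$variant, collapse = ", "))
  }
  chain <- chain %||% row$chain
  mutate_pair_chain(pair, chain, row$wt, row$position, row$mut,
                    sprintf("variant %s applied to chain %s", variant,
                            chain))
}

#' Ad-hoc chain mutation (bypasses design provenance)
#'
#' Applies an arbitrary point change to one chain of a pair, outside the
#' named-variant registry.  The design name is left untouched; the audit
#' log records the change as ad hoc.
#'
#' @param pair an [engineered_pair].
#' @param chain `"A"` or `"B"`.
#' @param change compact notation, e.g. `"K88A"` (wild-type must match the
#'   chain's current residue).
#' @return the modified [engineered_pair].
#' @export
mutate_chain <- function(pair, chain, change) {
  s <- parse_substitutions(change)
  if (nrow(s) != 1L) stop("mutate_chain() applies exactly one change")
  mutate_pair_chain(pair, chain, s$wt, s$position, s$mut,
                    sprintf("ad hoc mutation %s on chain %s", change,
                            chain))
}

mutate_pair_chain <- function(pair, chain, wt, position, mut, log_line) {
  chain <- toupper(chain)
  stopifnot(chain %in% c("A", "B"))
  slot <- if (chain == "A") "chain_a" else "chain_b"
  sslot <- if (chain == "A") "subs_a" else "subs_b"
  dom <- pair[[slot]]
  cur <- residue_at(dom, position, required = TRUE)
  if (cur != wt) {
    stop(sprintf("%s%s%s inapplicable on chain %s: residue at %s is %s",
                 wt, position, mut, chain, position, cur))
  }
  chars <- strsplit(dom$sequence, "")[[1]]
  chars[match(position, dom$labels)] <- mut
  pair[[slot]] <- numbered_domain(paste(chars, collapse = ""), dom$labels,
                                  dom$domain_class)
  subs <- pair[[sslot]]
  hit <- which(subs$position == position)
  if (length(hit) == 1L && subs$wt[hit] == mut) {
    subs <- subs[-hit, , drop = FALSE]       # undo: back to acceptor residue
  } else if (length(hit) == 1L) {
    subs$mut[hit] <- mut                     # recompose on top of a graft
  } else {
    subs <- rbind(subs, data.frame(wt = wt, position = position, mut = mut,
                                   stringsAsFactors = FALSE))
  }
  pair[[sslot]] <- substitution_list(subs$wt, subs$position, subs$mut)
  pair$rules_applied <- c(pair$rules_applied, log_line)
  pair$design_name <- paste0(pair$design_name,
                             if (!grepl("ad hoc", log_line))
                               sprintf(" [%s%s%s@%s]", wt, position, mut,
                                       chain)
                             else "")
  pair
}

#' Engineer Protein A binding into a CH4 domain
#'
#' CH4 domains do not bind Protein A; binding is conferred by the R115H and
#' V116Y substitutions (IMGT numbering), recreating the His/Tyr pair that
#' IgG presents at its Protein A elbow.  Applied to an [engineered_pair]
#' the rule is applied to both CH4 chains and the design name gains the
#' `"pA"` tag.
#'
#' @param x a [numbered_domain()] of a CH4 class, or an [engineered_pair]
#'   whose acceptor is CH4.
#' @return the engineered object; for a domain, the applied substitution
#'   list is in `attr(x, "substitutions")` and the audit tag in
#'   `attr(x, "audit")`.
#' @examples
#' pa <- add_protein_a_binding(reference_set()[["IgM-CH4"]])
#' residue_at(pa, c("115", "116"))
#' @export
add_protein_a_binding <- function(x) UseMethod("add_protein_a_binding")

.pa_subs <- function() substitution_list(c("R", "V"), c("115", "116"),
                                         c("H", "Y"))

#' @export
add_protein_a_binding.numbered_domain <- function(x) {
  if (domain_type(x$domain_class) != "CH4") {
    stop("Protein A engineering applies to CH4 domains, not ",
         x$domain_class)
  }
  out <- apply_substitutions(x, .pa_subs())
  attr(out, "substitutions") <- .pa_subs()
  attr(out, "audit") <- "pA"
  out
}

#' @export
add_protein_a_binding.engineered_pair <- function(x) {
  if (domain_type(x$acceptor_class) != "CH4") {
    stop("Protein A engineering applies to CH4 pairs, not ",
         x$acceptor_class)
  }
  for (slot in c("a", "b")) {
    dom <- x[[paste0("chain_", slot)]]
    x[[paste0("chain_", slot)]] <- apply_substitutions(dom, .pa_subs())
    subs <- x[[paste0("subs_", slot)]]
    subs <- rbind(subs, .pa_subs())
    x[[paste0("subs_", slot)]] <- substitution_list(subs$wt, subs$position,
                                                    subs$mut)
  }
  x$rules_applied <- c(x$rules_applied, "pA")
  x$design_name <- paste(x$design_name, "pA")
  x
}
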