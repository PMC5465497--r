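#' Packaged construct segments
#'
#' The human IgG1 hinge (`DKTHTCPPCP`) and the canonical human IgG1 CH2
#' sequence used to build Fc-like chains.  Like the domain references,
#' the CH2 entry is a curated canonical sequence packaged for construct
#' assembly, not a database export.
#'
#' @return named character vector with elements `hinge` and `ch2`.
#' @export
construct_segments <- function() {
  c(hinge = "DKTHTCPPCP",
    ch2 = paste0("APELLGGPSVFLFPPKPKDTLMISRTPEVTCVVVDVSHEDPEVKFNWYVDGV",
                 "EVHNAKTKPREEQYNSTYRVVSVLTVLHQDWLNGKEYKCKVSNKALPAPIEK",
                 "TISKAK"))
}

#' Construct template for Fc-like chains
#'
#' Ordered segments concatenated N- to C-terminal ahead of the engineered
#' CH3/CH4 domain: an optional fusion placeholder, the hinge and CH2.
#'
#' @param name template label.
#' @param hinge,ch2 segment sequences; defaults from
#'   [construct_segments()].
#' @return list of class `construct_template`.
#' @export
construct_template <- function(name = "fc-like",
                               hinge = construct_segments()[["hinge"]],
                               ch2 = construct_segments()[["ch2"]]) {
  for (s in c(hinge, ch2)) {
    if (!nzchar(s)) stop("empty template segment")
  }
  structure(list(name = name, hinge = hinge, ch2 = ch2),
            class = "construct_template")
}

#' Assemble Fc-like chains around an engineered pair
#'
#' Builds the two heavy chains of an Fc-like protein
#' (hinge - CH2 - engineered CH3/CH4), optionally fusing an N-terminal
#' domain (e.g. a VL domain antibody or an scFv) to exactly one chain so
#' the two species separate by molecular weight.  Each chain is annotated
#' with whether its CH3/CH4 module binds Protein A: an IgG3-derived CH3
#' does not, a CH4 only when Protein A binding was engineered (`pA`), any
#' other CH3 does.  The set-level tag `A(0)`/`A(+)`/`A(2+)` counts
#' binding-competent chains, the handle for differential Protein A
#' removal of homodimer contaminants.
#'
#' @param pair an [engineered_pair].
#' @param template a [construct_template()].
#' @param fusion optional amino-acid string fused N-terminally.
#' @param fusion_chain `"A"` or `"B"`: the chain receiving the fusion.
#' @param isotype_a,isotype_b Ig isotype providing each chain's CH3-side
#'   constant region (`"IgG1"` or `"IgG3"`); ignored for CH4 pairs.
#' @return list of class `chain_set` with per-chain sequences, segment
#'   boundaries and Protein A annotation.
#' @examples
#' cs <- assemble_fc_like(beat_design(), fusion = strrep("Q", 108))
#' cs$protein_a
#' @export
assemble_fc_like <- function(pair, template = construct_template(),
                             fusion = NULL, fusion_chain = "B",
                             isotype_a = "IgG1", isotype_b = "IgG1") {
  stopifnot(inherits(pair, "engineered_pair"),
            inherits(template, "construct_template"))
  fusion_chain <- toupper(fusion_chain)
  stopifnot(fusion_chain %in% c("A", "B"))
  is_ch4 <- domain_type(pair$acceptor_class) == "CH4"
  has_pa <- "pA" %in% pair$rules_applied
  binds <- function(isotype) {
    if (is_ch4) has_pa else !identical(isotype, "IgG3")
  }
  chains <- list()
  for (ch in c("A", "B")) {
    dom <- if (ch == "A") pair$chain_a else pair$chain_b
    isotype <- if (ch == "A") isotype_a else isotype_b
    segs <- c(hinge = template$hinge, ch2 = template$ch2,
              ch3 = dom$sequence)
    if (!is.null(fusion) && ch == fusion_chain) {
      segs <- c(fusion = toupper(fusion), segs)
    }
    chains[[ch]] <- list(sequence = paste(segs, collapse = ""),
                         segments = segs, isotype = isotype,
                         protein_a_binding = binds(isotype))
  }
  sites <- sum(vapply(chains, `[[`, NA, "protein_a_binding"))
  structure(list(design_name = pair$design_name, chains = chains,
                 protein_a = sprintf("A(%s)",
                                     c("0", "+", "2+")[sites + 1L]),
                 protein_a_sites = sites),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("<chain_set> ", x$design_name, "  [", x$protein_a, "]\n", sep = "")
  for (ch in names(x$chains)) {
    info <- x$chains[[ch]]
    cat(sprintf("  chain %s (%s%s): %d aa = %s\n", ch, info$isotype,
                if (info$protein_a_binding) ", binds Protein A" else
                  ", no Protein A",
                nchar(info$sequence),
                paste(sprintf("%s(%d)", names(info$segments),
                              nchar(info$segments)), collapse = " + ")))
  }
  invisible(x)
}

# Average residue masses (Da) of the 20 standard amino acids.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

#' Average polypeptide mass
#'
#' Sum of average residue masses plus one water, i.e. the unmodified
#' average isotopic mass of the polypeptide (no glycans or other PTMs).
#' The empty chain returns the mass of water.
#'
#' @param sequence amino-acid string.
#' @return mass in kDa.
#' @examples
#' chain_mass("G")   # glycine as a free amino acid, 0.0751 kDa
#' @export
chain_mass <- function(sequence) {
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)))
  if (nchar(sequence) == 0) return(.water_mass / 1000)
  letters1 <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(letters1, names(.residue_mass))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  }
  (sum(.residue_mass[letters1]) + .water_mass) / 1000
}
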