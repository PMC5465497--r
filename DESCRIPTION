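Package: igraft
Title: Interface Exchange Engineering of Immunoglobulin Constant-Domain
    Heterodimers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design toolkit for engineering heterodimeric immunoglobulin
    constant-domain pairs (Fc heterodimers for bispecific antibodies) by
    protein-protein interface exchange.  Assigns IMGT C-DOMAIN unique
    numbering to constant-domain sequences by alignment to curated
    references, grafts complete heterodimeric interfaces (e.g. T-cell
    receptor alpha/beta or gamma/delta constant-domain pairs) or
    half-interfaces from a second homodimer onto an acceptor homodimer,
    and emits per-chain substitution lists in IMGT coordinates.  Includes
    the structural-analysis companion used to design and validate such
    grafts: interdomain hydrophobic/ionic contact maps from PDB or mmCIF
    coordinates, least-squares C-alpha superposition with a reflection
    guard, and side-chain chi1 conservation scoring, together with
    deterministic synthetic sequence and structure fixtures, Fc-like and
    scFv x Fab chain assembly, and plain-text design reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
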