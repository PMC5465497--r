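---
title: "Designing Fc heterodimers by constant-domain interface exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Fc heterodimers by constant-domain interface exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igraft)
```

## The problem

A bispecific antibody built on the heavy-chain heterodimer architecture
needs two *different* heavy chains to pair with each other.  Left alone,
CH3 domains homodimerize: co-expressing two heavy chains yields a
statistical mixture of one heterodimer and two homodimers that is painful
to purify at scale.  Classical fixes (knobs-into-holes cavities,
strand-exchanged SEED domains) redesign the CH3 interface case by case.

Interface exchange takes a biomimetic shortcut: nature already built
heterodimeric Ig constant-domain pairs — the T-cell receptor constant
domains Ca/Cb and Cg/Cd.  Because every Ig constant domain shares the same
fold, the residues at structurally equivalent positions can be swapped
between domain pairs.  Grafting the interface residues of a natural
heterodimer onto both chains of an acceptor homodimer transplants the
donor's pairing preference; grafting *half* of a second homodimer's
interface onto one chain of the acceptor breaks its symmetry (a mixed
interface, MI, design).

## Coordinates: IMGT unique numbering for C-DOMAIN

Cross-class position equivalence is provided by the IMGT unique numbering
for C-DOMAIN.  Each reference domain in the package carries a full label
assignment on a shared 103-position scaffold (labels 1–45, 77–96 and
97–127, with the inserted positions 84.1–84.5 and 85.3–85.1 in the F–G
loop).  Chain order of the insertions follows the C-DOMAIN convention:
`84 < 84.1 < 84.2 < … < 85.2 < 85.1 < 85`; the comparator implements this
as a closed rule so that every label the package emits is strictly
ordered.  User sequences acquire numbering by global alignment
(BLOSUM62, affine gaps, identity floor 30%) to a packaged reference and
label transfer across aligned columns; insertions are flagged rather than
given invented labels, and a sequence that has lost any of the fifteen
interface positions is rejected outright, since it cannot take part in
interface exchange.

Alignment ties are resolved by the underlying pairwise aligner, which is
deterministic for fixed inputs — the property the design workflow needs
(identical inputs always yield byte-identical designs).

## The interface catalog

Fifteen beta-strand positions carry the interdomain interface of every
constant-domain pair examined here:

```{r}
interface_positions()
```

Four key sets of reciprocal positions do the symmetry breaking (88 of one
chain packs against 85.1/86 of the other; 20 packs against 26), while
positions 3, 5, 7, 22, 79, 81, 84, 84.2 and 90 support them.  For mixing
two homodimers the four sets collapse to a two-sided partition:

```{r}
interface_catalog()$half_side_1
interface_catalog()$half_side_2
```

## Generating designs

Two rules govern every graft.  *Skip-identical*: a substitution is
emitted only where donor and acceptor differ, so substitution lists stay
minimal and self-grafts are empty.  *Cys-avoidance*: a donor cysteine at
a grafted position is imported as alanine — an unpaired interface
cysteine would scramble the inter-chain disulfides — and the event is
logged in the design's audit trail.  The TCR Cb domain has a natural
cysteine at 85.1, which is why the packaged Ca/Cb graft carries `F85.1A`
on chain B rather than `F85.1C`:

```{r}
beat <- beat_design()
beat
```

`beat_min()` restricts the same graft to six chain-A and two chain-B
positions; `beat_gd()` uses the Cg/Cd donor pair over the same position
set; `beat_ch4()` grafts Ca/Cb onto the IgM CH4 homodimer.  Mixed
designs come from `half_interface_graft()` and are auto-named by the MI
convention (first letter: class donating position 88; second letter:
class donating 85.1/86):

```{r}
half_interface_graft(reference_set()[["IgG1-CH3"]],
                     reference_set()[["IgD-CH3"]])$design_name
```

Named variants (`Q3A`, `R90T`, `D84.4Q`, `W81T`) form a closed registry:
each checks the expected wild-type residue before applying, and undoing a
grafted substitution removes its list entry so the substitution list and
the chain sequence can never drift apart.  Arbitrary changes go through
`mutate_chain()`, which deliberately bypasses design provenance.
`add_protein_a_binding()` applies R115H/V116Y to CH4 domains,
reconstructing the His/Tyr elbow that Protein A recognizes on IgG;
conversely the IgG3 CH3 (R/F at 115/116) is the package's handle for
*removing* Protein A binding from one chain of an assembled construct,
so that residual homodimers separate chromatographically.

## Packaged references are curated reconstructions

The nine reference domains (IgG1/IgG3/IgA/IgD CH3, IgM CH4, TCR
Ca/Cb/Cg/Cd) are shipped as FASTA plus a numbering sidecar, with
`synthetic` in the file names.  The IgG1 CH3 entry is the canonical human
IGHG1 CH3 sequence.  The remaining entries follow their germline gene
flavour but are *curated*: at every position where a packaged design
implies a wild-type letter (the documented substitution lists, the
variant registry, the Protein A elbow), the reference must carry that
letter.  This contract is enforced by `check_reference_consistency()` on
every load — if a reference were edited into disagreement, the package
fails loudly rather than silently emitting a deviant design.  Residues
outside the constrained columns are plausible but not authoritative;
anyone reproducing designs against their own constructs should number
their actual sequences with `assign_imgt_numbering()` rather than rely on
the packaged scaffolds' unconstrained columns.

## The structural companion

Designs of this kind are validated structurally, so the package carries
the three kernels that analysis needs.

**Contact maps.** `compute_contacts()` reports two interaction kinds per
interdomain residue pair, in the style of residue-interaction servers:
hydrophobic (side-chain carbons of Ala, Val, Leu, Ile, Met, Phe, Trp,
Pro, Tyr within 5.0 Å across chains) and ionic (side-chain N/O of Lys,
Arg, His within 6.0 Å of side-chain O of Asp, Glu).  Both cutoffs are
configurable through `contact_criteria()`.  The map stores the minimal
qualifying atom–atom distance per residue pair, is invariant to chain
argument order, and renders to a deterministic text diagram that flags
symmetric pairs — the hallmark of a homodimeric interface — versus the
asymmetric contacts a heterodimer design aims to create.

**Superposition.** `kabsch()` computes the least-squares rigid
superposition via SVD with a determinant guard, so reflections are never
returned even for degenerate (collinear) selections.
`superpose_calpha()` pairs C-alpha atoms between models by shared IMGT
position where chains are annotated, else by residue number, and reports
the RMSD in Å.

**Side-chain conservation.** Whether a grafted residue "kept its donor
orientation" is operationalized as the chi1 dihedral (N–CA–CB–gamma)
agreeing within a tolerance, 60° by default — chi1 classifies rotamers
into the three classical wells, so 60° separates well boundaries without
punishing thermal jitter.  This criterion is a declared choice of this
package, not a community standard: published statements about
orientation conservation rarely state their criterion, so comparisons at
the decimal level are not meaningful.  Residues without a chi1 (Gly, Ala)
count as conserved; positions with unresolved atoms are excluded from the
denominator and reported, never silently dropped.  Because chi1 is an
internal coordinate the score needs no prior superposition, and it is
monotone non-increasing as the tolerance shrinks.

Structures are read from PDB (via bio3d) or mmCIF (a minimal `atom_site`
reader written for this package, as no installed R package parses mmCIF).
First model only, altloc `A` preferred, hydrogens ignored, Å units.

## Synthetic fixtures

Every kernel is testable offline through deterministic toy structures:
`build_residue()` places idealized residues (canonical bond lengths and
angles, only the atoms the criteria need) with an adjustable chi1, and
`make_contact_fixture()` assembles two-chain models whose minimal
qualifying atom-atom distances match a requested value within 0.01 Å,
with pairs spaced 40 Å apart so they cannot cross-talk, and an optional
seeded rigid motion of the whole model.  What these fixtures emulate is
the *geometry* the kernels measure; they are not physically realistic
proteins (no packing, no Ramachandran statistics, no solvent), so tests
passing on fixtures demonstrate kernel correctness, not force-field
quality.  Crystal-structure checks against deposited entries are
available in the accession-gated part of the test suite, which downloads
coordinates only when `IGRAFT_FETCH_STRUCTURES=true` is set.

## Construct assembly and reporting

`assemble_fc_like()` concatenates hinge (`DKTHTCPPCP`), IgG1 CH2 and an
engineered CH3/CH4 into Fc-like chains, optionally fusing an N-terminal
domain to one chain so hetero- and homodimers separate by molecular
weight on a gel; `chain_mass()` supplies the average polypeptide mass
(no glycans).  Protein A competence is annotated per chain from static
isotype rules — it is a bookkeeping tag, not a binding predictor.  The
scFv linker and fusion-domain sequences of any real construct are
project-specific; the assembler takes them as plain sequence arguments
rather than shipping placeholders as if they were canonical.

## Numerical and testing choices

Test problem sizes are chosen to exercise the mathematics at negligible
cost: 10-point clouds for superposition (the brute-force Euler-grid
oracle agrees with the SVD solution to better than 1e-3 Å there), 100
randomized contact fixtures per property run, and full-domain toy
structures of 103 residues.  The grid oracle uses a 15° coarse scan
refined through ten shrinking windows, which is enough to sit ~1e-11 Å
above the analytic optimum.  Substitution lists are kept sorted in chain
order, rendered in compact notation (`S20K`, `F85.1A`), and every design
object satisfies the round-trip invariant — applying a chain's list to
the acceptor reproduces the chain sequence exactly — which the test suite
asserts for all packaged designs.

## Limitations

The package designs sequences and analyzes structures; it does not
predict heterodimerization efficiency, expression, thermal stability or
immunogenicity — those are experimental observables.  It does not build
homology models; the contact kernel accepts any coordinates but model
generation is out of scope, as are hydrogen-bond and cation-pi detection
beyond the two contact kinds the interface diagrams report.  Numbering is
for constant domains only: no V-domain or CDR support, and
alignment-to-reference (not a profile HMM) is the transfer mechanism,
which is adequate at C-domain identity levels but not for remote
homologs.
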