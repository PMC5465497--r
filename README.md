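# igraft

Interface exchange engineering of immunoglobulin constant-domain
heterodimers, in R.

## What problem this solves, and for whom

Bispecific antibodies built as heavy-chain heterodimers need two
*different* heavy chains to pair preferentially with each other.
Unengineered CH3 domains homodimerize, so co-expression yields a mixture
of the wanted heterodimer and two homodimer contaminants.  `igraft` is
for antibody engineers who want to generate such heterodimer designs
systematically rather than case by case: it implements **interface
exchange**, where the interface residues of an acceptor homodimer
(IgG1 CH3 or IgM CH4) are replaced by the residues found at the
structurally equivalent positions of a donor interface — a natural
heterodimer (TCR Ca/Cb or Cg/Cd constant-domain pairs) or half of a
second homodimer's interface (IgA, IgD, IgG1 or IgM; a "mixed
interface" design).

Structural equivalence across Ig classes and TCRs comes from the IMGT
unique numbering for C-DOMAIN.  The fifteen interface positions are

```
3, 5, 7, 20, 22, 26, 27, 79, 81, 84, 84.2, 85.1, 86, 88, 90
```

with the C-DOMAIN insertion order `84 < 84.1 < 84.2 < ... < 85.2 < 85.1
< 85`.  A design is an `engineered_pair`: two engineered chain sequences
plus per-chain substitution lists in compact IMGT notation (`S20K`,
`F85.1A`), generated under two rules — *skip-identical* (substitute only
where donor and acceptor differ) and *cys-avoidance* (a donor interface
cysteine is imported as alanine, logged).

The package also carries the structural-analysis companion used to
design and validate grafts: PIC-style interdomain contact maps
(hydrophobic pairs within 5 Å, ionic pairs within 6 Å), least-squares
C-alpha superposition (Kabsch SVD with a reflection guard), side-chain
chi1 conservation scoring, PDB/mmCIF reading, deterministic synthetic
fixtures, Fc-like chain assembly and plain-text design reports.

## Worked example

```r
library(igraft)

beat <- beat_design()   # TCR Ca/Cb interface grafted onto IgG1 CH3
beat
#> <engineered_pair> BEAT
#>   acceptor: IgG1-CH3; donors: TCR-Ca / TCR-Cb
#>   chain A: 8 substitution(s): S20K, T22V, K26T, K79Y, F85.1S, Y86V, K88W, T90N
#>   chain B: 13 substitution(s): Q3E, Y5A, L7F, S20T, T22V, K26T, T81D, V84L, D84.2E, F85.1A, Y86S, K88R, T90R
#>   rules:
#>     - skip-identical
#>     - cys-avoidance [chain B]: donor TCR-Cb Cys at 85.1 -> Ala
```

Chain A carries the TCR Ca residues at the eight interface positions
where Ca differs from IgG1 CH3 (e.g. `K88W`, the tryptophan that packs
into the partner chain); chain B carries the Cb residues, with the
natural Cb cysteine at 85.1 imported as alanine.  Variants from the
closed registry refine a design; homodimer-destabilizing `D84.4Q` on
chain B, for example:

```r
format_substitutions(apply_variant(beat, "D84.4Q")$subs_b)
#>  [1] "Q3E"    "Y5A"    "L7F"    "S20T"   "T22V"   "K26T"   "T81D"
#>  [8] "V84L"   "D84.2E" "D84.4Q" "F85.1A" "Y86S"   "K88R"   "T90R"
```

Mixing two homodimers instead (half-interface graft, auto-named by the
MI convention):

```r
half_interface_graft(reference_set()[["IgG1-CH3"]],
                     reference_set()[["IgD-CH3"]])
#> <engineered_pair> MI (CH3) DG/GD
#>   acceptor: IgG1-CH3; donors: IgD-CH3 / IgD-CH3
#>   chain A: 5 substitution(s): S20Q, K79S, T81I, K88E, T90S
#>   chain B: 7 substitution(s): Q3T, Y5F, K26N, V84A, D84.2N, F85.1V, Y86W
```

Chain 1 is substituted only at positions 20/79/81/88/90, chain 2 only at
3/5/26/84/84.2/85.1/86 — the two halves of a symmetric interface.
Finally, assemble Fc-like chains with an N-terminal fusion for a
molecular-weight signature and an IgG3-derived chain A for asymmetric
Protein A purification:

```r
assemble_fc_like(beat, fusion = strrep("Q", 108), isotype_a = "IgG3")
#> <chain_set> BEAT  [A(+)]
#>   chain A (IgG3, no Protein A): 223 aa = hinge(10) + ch2(110) + ch3(103)
#>   chain B (IgG1, binds Protein A): 331 aa = fusion(108) + hinge(10) + ch2(110) + ch3(103)
```

`A(+)` records that exactly one chain binds Protein A, the handle for
chromatographic removal of homodimer traces.  A thin command-line
wrapper over the same functions is installed as `exec/igraft`
(verbs: `number`, `graft`, `variant`, `assemble`, `contacts`,
`superpose`, `report`).

Note on the packaged references: the nine reference domains are curated
reconstructions (the IgG1 CH3 entry is the canonical human sequence; the
others follow their germline flavour and are pinned at every
design-relevant column, a contract re-checked on every load).  See the
methods vignette (`vignettes/interface-exchange.Rmd`) for the science,
the parameter choices and the limitations.

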