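refs <- reference_set()
g1 <- refs[["IgG1-CH3"]]

test_that("the TCR Ca/Cb graft reproduces the documented CH3 design", {
  pair <- beat_design(refs)
  expect_identical(format_substitutions(pair$subs_a),
                   c("S20K", "T22V", "K26T", "K79Y", "F85.1S", "Y86V",
                     "K88W", "T90N"))
  expect_identical(format_substitutions(pair$subs_b),
                   c("Q3E", "Y5A", "L7F", "S20T", "T22V", "K26T", "T81D",
                     "V84L", "D84.2E", "F85.1A", "Y86S", "K88R", "T90R"))
  # the donor cysteine at 85.1 was imported as alanine, and logged
  expect_true(any(grepl("cys-avoidance", pair$rules_applied)))
  expect_identical(residue_at(pair$chain_b, "85.1"), "A")
})

test_that("self-graft emits no substitutions", {
  pair <- full_interface_graft(g1, g1, g1)
  expect_identical(nrow(pair$subs_a), 0L)
  expect_identical(nrow(pair$subs_b), 0L)
  expect_identical(pair$chain_a$sequence, g1$sequence)
})

test_that("the CH4 graft equals a per-position donor lookup oracle", {
  pair <- beat_ch4(refs)
  ch4 <- refs[["IgM-CH4"]]
  for (side in list(list(donor = refs[["TCR-Ca"]], subs = pair$subs_a),
                    list(donor = refs[["TCR-Cb"]], subs = pair$subs_b))) {
    expected <- NULL
    for (p in interface_positions()) {
      wt <- residue_at(ch4, p)
      mut <- residue_at(side$donor, p)
      if (mut == "C") mut <- "A"
      if (mut != wt) {
        expected <- rbind(expected, data.frame(wt = wt, position = p,
                                               mut = mut))
      }
    }
    expected <- substitution_list(expected$wt, expected$position,
                                  expected$mut)
    expect_identical(side$subs, expected)
  }
})

test_that("grafting is deterministic, idempotent and local", {
  p1 <- beat_design(refs); p2 <- beat_design(refs)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  # re-grafting an engineered chain with the same donor adds nothing
  again <- full_interface_graft(p1$chain_a, refs[["TCR-Ca"]],
                                refs[["TCR-Cb"]])
  expect_identical(nrow(again$subs_a), 0L)
  # positions outside the graft set are never altered
  outside <- setdiff(domain_positions(g1), interface_positions())
  expect_identical(residue_at(p1$chain_a, outside),
                   residue_at(g1, outside))
  expect_identical(residue_at(p1$chain_b, outside),
                   residue_at(g1, outside))
})

test_that("no emitted substitution is trivial or introduces a cysteine", {
  designs <- list(beat_design(refs), beat_min(refs), beat_gd(refs),
                  beat_ch4(refs),
                  half_interface_graft(g1, refs[["IgA-CH3"]]),
                  half_interface_graft(g1, refs[["IgD-CH3"]]),
                  half_interface_graft(g1, refs[["IgM-CH4"]]),
                  half_interface_graft(refs[["IgM-CH4"]], g1))
  for (pair in designs) {
    for (subs in list(pair$subs_a, pair$subs_b)) {
      expect_false(any(subs$wt == subs$mut))
      expect_false(any(subs$mut == "C"))
    }
    # round-trip: applying the lists to the acceptor rebuilds the chains
    expect_identical(apply_substitutions(pair$acceptor,
                                         pair$subs_a)$sequence,
                     pair$chain_a$sequence, label = pair$design_name)
    expect_identical(apply_substitutions(pair$acceptor,
                                         pair$subs_b)$sequence,
                     pair$chain_b$sequence, label = pair$design_name)
  }
})

test_that("the reduced design is contained in the full graft", {
  full <- beat_design(refs); min_ <- beat_min(refs)
  expect_identical(format_substitutions(min_$subs_a),
                   c("S20K", "T22V", "K26T", "K79Y", "K88W", "T90N"))
  expect_identical(format_substitutions(min_$subs_b),
                   c("F85.1A", "Y86S"))
  expect_true(all(format_substitutions(min_$subs_a) %in%
                    format_substitutions(full$subs_a)))
  expect_true(all(format_substitutions(min_$subs_b) %in%
                    format_substitutions(full$subs_b)))
})

test_that("the Cg/Cd graft covers the same position set as the Ca/Cb one", {
  gd <- beat_gd(refs); beat <- beat_design(refs)
  expect_identical(gd$subs_a$position, beat$subs_a$position)
  expect_identical(gd$subs_b$position, beat$subs_b$position)
  expect_gt(nrow(gd$subs_a), 0)
  expect_gt(nrow(gd$subs_b), 0)
  expect_false(identical(format_substitutions(gd$subs_a),
                         format_substitutions(gd$subs_b)))
  # per-position residue identities come straight from the donor pair
  for (side in list(list(donor = refs[["TCR-Cg"]], subs = gd$subs_a),
                    list(donor = refs[["TCR-Cd"]], subs = gd$subs_b))) {
    mut <- residue_at(side$donor, side$subs$position)
    mut[mut == "C"] <- "A"
    expect_identical(side$subs$mut, mut)
  }
})

test_that("half-interface designs respect the partition and naming", {
  cat_ <- interface_catalog()
  mi <- half_interface_graft(g1, refs[["IgD-CH3"]])
  expect_identical(mi$design_name, "MI (CH3) DG/GD")
  expect_true(all(mi$subs_a$position %in% cat_$half_side_1))
  expect_true(all(mi$subs_b$position %in% cat_$half_side_2))
  # residue identities from the packaged IgD donor
  expect_identical(mi$subs_a$mut,
                   residue_at(refs[["IgD-CH3"]], mi$subs_a$position))
  expect_identical(mi$subs_b$mut,
                   residue_at(refs[["IgD-CH3"]], mi$subs_b$position))
  mi4 <- half_interface_graft(refs[["IgM-CH4"]], g1)
  expect_identical(mi4$design_name, "MI (CH4) GM/MG")
  # self-mix is empty
  self_mix <- half_interface_graft(g1, g1)
  expect_identical(nrow(self_mix$subs_a) + nrow(self_mix$subs_b), 0L)
  # heterodimer-forming classes cannot be mixed
  expect_error(half_interface_graft(g1, refs[["TCR-Ca"]]),
               "homodimer")
})

test_that("missing positions are reported with the offending domain", {
  # first 60 residues: positions 85.1 onward are absent
  short <- numbered_domain(substr(g1$sequence, 1, 60),
                           g1$labels[1:60], "custom")
  expect_error(full_interface_graft(short, refs[["TCR-Ca"]],
                                    refs[["TCR-Cb"]]),
               "custom lacks requested position")
  expect_error(full_interface_graft(g1, refs[["TCR-Ca"]],
                                    refs[["TCR-Cb"]],
                                    positions_a = "115"),
               "outside the interface catalog")
})
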