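test_that("ionic and hydrophobic contacts follow their cutoffs", {
  m <- make_contact_fixture(list(
    list(res_i = "LYS", res_j = "GLU", distance = 3.5),
    list(res_i = "LEU", res_j = "LEU", distance = 4.5)
  ))
  map <- compute_contacts(m, c("A", "B"))
  expect_identical(map$kind, c("hydrophobic", "ionic"))
  expect_equal(map$min_distance, c(4.5, 3.5), tolerance = 1e-6)
  # the same ionic pair beyond the 6 A cutoff: empty map, not an error
  far <- make_contact_fixture(list(list(res_i = "LYS", res_j = "GLU",
                                        distance = 7.0)))
  expect_identical(nrow(compute_contacts(far, c("A", "B"))), 0L)
  # a leucine pair outside the 5 A hydrophobic cutoff
  far2 <- make_contact_fixture(list(list(res_i = "LEU", res_j = "LEU",
                                         distance = 5.4)))
  expect_identical(nrow(compute_contacts(far2, c("A", "B"))), 0L)
})

test_that("contact maps are invariant to chain argument order", {
  m <- make_contact_fixture(list(
    list(res_i = "ARG", res_j = "ASP", distance = 4.0),
    list(res_i = "PHE", res_j = "VAL", distance = 4.2)
  ), seed = 5)
  ab <- compute_contacts(m, c("A", "B"))
  ba <- compute_contacts(m, c("B", "A"))
  expect_identical(as.data.frame(ab), as.data.frame(ba))
})

test_that("the contact kernel equals the brute-force all-pairs scan", {
  residues <- list(pos = c("LYS", "ARG"), neg = c("GLU", "ASP"),
                   hyd = c("LEU", "VAL", "PHE", "MET", "ALA"))
  set.seed(101)
  for (rep in 1:20) {
    pairs <- lapply(seq_len(sample(2:5, 1)), function(i) {
      if (stats::runif(1) < 0.5) {
        list(res_i = sample(residues$pos, 1),
             res_j = sample(residues$neg, 1),
             distance = stats::runif(1, 2.5, 8))
      } else {
        list(res_i = sample(residues$hyd, 1),
             res_j = sample(residues$hyd, 1),
             distance = stats::runif(1, 2.5, 8))
      }
    })
    m <- make_contact_fixture(pairs, seed = rep)
    got <- compute_contacts(m, c("A", "B"))
    want <- brute_force_contacts(m, c("A", "B"))
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_identical(got$kind, want$kind)
      expect_identical(got$resno_i, want$resno_i)
      expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
    }
  }
})

test_that("missing chains error; annotation propagates into the map", {
  refs <- reference_set()
  mini <- numbered_domain(substr(refs[["IgG1-CH3"]]$sequence, 1, 90),
                          refs[["IgG1-CH3"]]$labels[1:90], "custom")
  m <- make_contact_fixture(list(list(res_i = "LYS", res_j = "GLU",
                                      distance = 3.2)))
  expect_error(compute_contacts(m, c("A", "C")), "chain C absent")
  m$imgt[["A"]] <- data.frame(resno = 1L, imgt = "26")
  m$imgt[["B"]] <- data.frame(resno = 1L, imgt = "13")
  map <- compute_contacts(m, c("A", "B"))
  expect_identical(map$imgt_i, "26")
  expect_identical(map$imgt_j, "13")
})

test_that("interface diagrams are deterministic and flag symmetry", {
  # symmetric Lys26/Glu13 style pair: both reciprocal orientations present
  m <- make_contact_fixture(list(
    list(res_i = "LYS", res_j = "GLU", distance = 3.5),
    list(res_i = "GLU", res_j = "LYS", distance = 3.5)
  ))
  m$imgt[["A"]] <- data.frame(resno = 1:2, imgt = c("26", "13"))
  m$imgt[["B"]] <- data.frame(resno = 1:2, imgt = c("13", "26"))
  map <- compute_contacts(m, c("A", "B"))
  expect_identical(nrow(map), 2L)
  lines <- render_interface_diagram(map)
  expect_identical(lines, render_interface_diagram(map))  # pure function
  expect_identical(sum(grepl("\\[symmetric\\]", lines)), 2L)
  # one-sided contact is asymmetric
  single <- make_contact_fixture(list(list(res_i = "LYS", res_j = "GLU",
                                           distance = 3.5)))
  single$imgt[["A"]] <- data.frame(resno = 1L, imgt = "26")
  single$imgt[["B"]] <- data.frame(resno = 1L, imgt = "13")
  expect_true(any(grepl("\\[asymmetric\\]",
                        render_interface_diagram(
                          compute_contacts(single, c("A", "B"))))))
  # empty map still renders a header
  empty <- compute_contacts(make_contact_fixture(list(
    list(res_i = "LYS", res_j = "GLU", distance = 9))), c("A", "B"))
  expect_identical(render_interface_diagram(empty)[1],
                   "Interface contacts (0)")
})

test_that("PDB and mmCIF readers agree on the same model", {
  m <- make_contact_fixture(list(list(res_i = "LYS", res_j = "GLU",
                                      distance = 3.5)), seed = 3)
  pdb <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, pdb)
  from_pdb <- read_structure(pdb)
  expect_identical(from_pdb$atoms$atom, m$atoms$atom)
  expect_equal(as.matrix(from_pdb$atoms[, c("x", "y", "z")]),
               round(as.matrix(m$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
  cif <- tempfile(fileext = ".cif")
  at <- m$atoms
  writeLines(c(
    "data_fixture", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.label_alt_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s %s %s %d . %.3f %.3f %.3f 1",
            seq_len(nrow(at)), at$element, at$atom, at$resname, at$chain,
            at$resno, at$x, at$y, at$z),
    "#"), cif)
  from_cif <- read_structure(cif)
  expect_identical(from_cif$atoms$atom, from_pdb$atoms$atom)
  expect_equal(from_cif$atoms$x, from_pdb$atoms$x, tolerance = 1e-9)
  map_cif <- compute_contacts(from_cif, c("A", "B"))
  expect_equal(map_cif$min_distance, 3.5, tolerance = 1e-3)
})

test_that("structures built from a reference annotate completely", {
  refs <- reference_set()
  g1 <- refs[["IgG1-CH3"]]
  s <- make_domain_structure(g1, "A")
  ann <- annotate_structure(s, g1, "A")
  expect_true(all(interface_positions() %in% ann$imgt[["A"]]$imgt))
  # position 88 annotates a lysine
  r88 <- resno_of(ann, "A", "88")
  expect_identical(unique(ann$atoms$resname[ann$atoms$resno == r88 &
                                              ann$atoms$chain == "A"]),
                   "LYS")
  # two unmodeled terminal residues: annotation succeeds, termini absent
  trunc <- structure_model(s$atoms[s$atoms$resno >= 3, ])
  ann2 <- annotate_structure(trunc, g1, "A")
  expect_false("1" %in% ann2$imgt[["A"]]$imgt)
  expect_true("88" %in% ann2$imgt[["A"]]$imgt)
})
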