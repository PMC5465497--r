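refs <- reference_set()
g1 <- refs[["IgG1-CH3"]]

test_that("numbering a reference against itself is the identity", {
  dom <- assign_imgt_numbering(g1$sequence, g1)
  expect_identical(dom$labels, g1$labels)
  expect_length(attr(dom, "insertions"), 0)
})

test_that("numbering transfer is idempotent across all references", {
  for (cl in names(refs)) {
    dom <- assign_imgt_numbering(refs[[cl]]$sequence, refs[[cl]])
    expect_identical(dom$labels, refs[[cl]]$labels, label = cl)
  }
})

test_that("non-interface substitutions keep interface numbering, vs DP oracle", {
  # three changes away from the interface catalog
  mut <- make_mutant_sequence(g1, c("30" = "A", "95" = "D", "120" = "W"))
  dom <- assign_imgt_numbering(mut, g1)
  expect_identical(residue_at(dom, interface_positions()),
                   residue_at(g1, interface_positions()))
  expect_identical(dom$labels[!is.na(dom$labels)],
                   g1$labels[!is.na(g1$labels)])
  # independent unit-score dynamic-programming alignment gives the same map
  map <- nw_align_map(mut, g1$sequence)
  oracle_labels <- g1$labels[map]
  expect_identical(dom$labels, oracle_labels)
})

test_that("labeled positions are always a subset of the reference's", {
  set.seed(11)
  for (k in 1:10) {
    n_mut <- sample(1:6, 1)
    pos <- sample(nchar(g1$sequence), n_mut)
    chars <- strsplit(g1$sequence, "")[[1]]
    chars[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_mut,
                         replace = TRUE)
    dom <- assign_imgt_numbering(paste(chars, collapse = ""), g1)
    expect_true(all(domain_positions(dom) %in% domain_positions(g1)))
  }
})

test_that("terminal truncation is tolerated but interface loss is not", {
  # drop 2 N-terminal and 5 C-terminal residues: fine, termini unlabeled
  trimmed <- substr(g1$sequence, 3, nchar(g1$sequence) - 5)
  dom <- assign_imgt_numbering(trimmed, g1)
  expect_false("1" %in% domain_positions(dom))
  expect_false("127" %in% domain_positions(dom))
  expect_identical(residue_at(dom, "88"), "K")
  # delete the region carrying positions 86-90: explicit interface error
  i86 <- match("86", g1$labels); i90 <- match("90", g1$labels)
  gone <- paste0(substr(g1$sequence, 1, i86 - 1),
                 substr(g1$sequence, i90 + 1, nchar(g1$sequence)))
  expect_error(assign_imgt_numbering(gone, g1),
               "missing interface position")
})

test_that("inserted residues are flagged and unlabeled", {
  ins_at <- match("40", g1$labels)
  seq <- paste0(substr(g1$sequence, 1, ins_at), "GGG",
                substr(g1$sequence, ins_at + 1, nchar(g1$sequence)))
  dom <- assign_imgt_numbering(seq, g1)
  expect_length(attr(dom, "insertions"), 3)
  expect_true(all(is.na(dom$labels[attr(dom, "insertions")])))
  expect_identical(residue_at(dom, interface_positions()),
                   residue_at(g1, interface_positions()))
})

test_that("unrecognizable and out-of-range sequences are rejected", {
  expect_error(assign_imgt_numbering(strrep("GA", 50), g1),
               "not a recognizable C-domain")
  expect_error(assign_imgt_numbering(strrep("A", 50), g1), "length")
  expect_error(assign_imgt_numbering(strrep("A", 150), g1), "length")
})

test_that("numbered_domain enforces its invariants", {
  expect_error(numbered_domain("ACD", c("1", "2")), "does not match")
  expect_error(numbered_domain("ACD", c("1", "1", "2")), "duplicated")
  expect_error(numbered_domain("ACD", c("2", "1", "3")),
               "strictly increasing")
  # iterating positions in chain order reproduces the sequence
  dom <- refs[["TCR-Cb"]]
  ord <- order(imgt_key(domain_positions(dom)))
  expect_identical(paste(residue_at(dom, domain_positions(dom)[ord]),
                         collapse = ""),
                   dom$sequence)
})
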