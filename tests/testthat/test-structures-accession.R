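# Structural validation against deposited crystal structures.  These
# checks need the actual PDB entries; downloads are attempted only when
# explicitly enabled (IGRAFT_FETCH_STRUCTURES=true).  Everything else in
# the suite runs on packaged or generated material.

fetch_or_skip <- function(accession) {
  skip_if_not(structure_fetch_enabled(),
              "structure downloads not enabled (IGRAFT_FETCH_STRUCTURES)")
  path <- tryCatch(fetch_structure(accession),
                   error = function(e) NULL)
  skip_if(is.null(path), paste("could not fetch", accession))
  read_structure(path)
}

# Annotates both chains of an Fc(-like) model against the engineered or
# wild-type CH3 reference and returns the model.
annotate_ch3_chains <- function(model, chains, reference) {
  for (ch in chains) {
    model <- annotate_structure(model, reference, ch, min_identity = 0.5)
  }
  model
}

test_that("the engineered CH3 pair superposes onto a natural Fc at ~0.66 A", {
  beat <- fetch_or_skip("5M3V")
  wah <- fetch_or_skip("2WAH")
  g1 <- reference_set()[["IgG1-CH3"]]
  pick_chains <- function(model) {
    tab <- table(model$atoms$chain[model$atoms$atom == "CA"])
    names(sort(tab, decreasing = TRUE))[1:2]
  }
  cb <- pick_chains(beat); cw <- pick_chains(wah)
  beat <- annotate_ch3_chains(beat, cb, g1)
  wah <- annotate_ch3_chains(wah, cw, g1)
  fits <- c(
    superpose_calpha(beat, wah, cb, cw)$rmsd,
    superpose_calpha(beat, wah, cb, rev(cw))$rmsd
  )
  expect_equal(min(fits), 0.66, tolerance = 0.05 / 0.66)
})

test_that("grafted residues keep their donor chi1 in the solved structure", {
  beat <- fetch_or_skip("5M3V")
  kgc <- fetch_or_skip("1KGC")
  refs <- reference_set()
  g1 <- refs[["IgG1-CH3"]]
  chains <- unique(beat$atoms$chain[beat$atoms$atom == "CA"])[1:2]
  beat <- annotate_ch3_chains(beat, chains, g1)
  # the chain carrying Trp at 88 is the Ca-based chain A
  is_a <- vapply(chains, function(ch) {
    r <- resno_of(beat, ch, "88")
    !is.na(r) && unique(beat$atoms$resname[beat$atoms$chain == ch &
                                             beat$atoms$resno == r]) ==
      "TRP"
  }, NA)
  skip_if(sum(is_a) != 1, "could not orient the engineered chains")
  chain_a <- chains[is_a]; chain_b <- chains[!is_a]
  # locate the TCR constant domains in 1KGC
  tcr_chains <- unique(kgc$atoms$chain[kgc$atoms$atom == "CA"])
  find_chain <- function(ref) {
    for (ch in tcr_chains) {
      ok <- tryCatch({
        kgc <<- annotate_structure(kgc, ref, ch, min_identity = 0.5)
        TRUE
      }, error = function(e) FALSE)
      if (ok && !is.na(resno_of(kgc, ch, "88"))) return(ch)
    }
    NA_character_
  }
  ca_chain <- find_chain(refs[["TCR-Ca"]])
  cb_chain <- find_chain(refs[["TCR-Cb"]])
  skip_if(is.na(ca_chain) || is.na(cb_chain),
          "could not annotate the TCR constant domains")
  beat_pair <- beat_design(refs)
  scored <- c()
  for (side in list(list(bc = chain_a, kc = ca_chain,
                         pos = beat_pair$subs_a$position),
                    list(bc = chain_b, kc = cb_chain,
                         pos = beat_pair$subs_b$position))) {
    frac <- sidechain_conservation(beat, kgc, side$pos, side$bc, side$kc)
    d <- attr(frac, "detail")
    scored <- rbind(scored, d[d$status != "excluded", ])
  }
  overall <- mean(scored$status == "conserved")
  expect_equal(overall, 0.85, tolerance = 0.05 / 0.85)
})

test_that("the natural CH3 interface shows its hallmark symmetric contacts", {
  fc <- fetch_or_skip("1H3T")
  g1 <- reference_set()[["IgG1-CH3"]]
  chains <- unique(fc$atoms$chain[fc$atoms$atom == "CA"])[1:2]
  fc <- annotate_ch3_chains(fc, chains, g1)
  map <- compute_contacts(fc, chains)
  ionic <- map[map$kind == "ionic", ]
  # Lys26/Glu13 on both sides of the interface
  expect_true(any(ionic$imgt_i == "26" & ionic$imgt_j == "13",
                  na.rm = TRUE))
  expect_true(any(ionic$imgt_i == "13" & ionic$imgt_j == "26",
                  na.rm = TRUE))
  # Tyr86 symmetric hydrophobic contact
  hyd <- map[map$kind == "hydrophobic", ]
  expect_true(any(hyd$imgt_i == "86" & hyd$imgt_j == "86", na.rm = TRUE))
  lines <- render_interface_diagram(map)
  expect_true(any(grepl("26 .* 13|13 .* 26", lines)))
})
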