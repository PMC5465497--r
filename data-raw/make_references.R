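# Builds the packaged C-domain reference set (FASTA + IMGT numbering sidecar TSV).
#
# The sequences are curated reconstructions: the IgG1 CH3 entry is the canonical
# human IGHG1 CH3 sequence; the remaining entries follow their germline gene
# flavour but are curated at interface columns so that every wild-type letter
# implied by the packaged designs holds.  Each reference uses one shared
# 103-column label scaffold (no per-reference insertions), which keeps
# alignment-and-transfer exact for packaged material.  Run from the package
# root: Rscript data-raw/make_references.R

label_scaffold <- c(
  as.character(1:45),
  as.character(77:84),
  "84.1", "84.2", "84.3", "84.4", "84.5", "85.3", "85.2", "85.1", "85",
  as.character(86:111),
  as.character(113:127)
)
stopifnot(length(label_scaffold) == 103L, !anyDuplicated(label_scaffold))

seqs <- c(
  `IgG1-CH3` = paste0(
    "EPQVYTLPPSRDELTKNQVSLTCLVKGFYPSDIAVEWESNGQPEN",
    "NYKTTPPV", "LDSDGSFFL",
    "YSKLTVDKSRWQQGNVFSCSVMHEAL", "HNHYTQKSLSLSPGK"),
  # IgG3: IgG1 CH3 with the class-distinguishing residues, most importantly the
  # R/F Protein-A elbow (positions 115/116) that abolishes Protein A binding.
  `IgG3-CH3` = paste0(
    "EPQVYTLPPSREEMTKNQVSLTCLVKGFYPSDIAVEWESSGQPEN",
    "NYKTTPPV", "LDSDGSFFL",
    "YSKLTVDKSRWQQGNIFSCSVMHEAL", "HNRFTQKSLSLSPGK"),
  `TCR-Ca` = paste0(
    "IQQVYQLRDS", "KSSDTSNSD", "KSVCLFTGFDS", "QTNVSQSKDSDVYIT",
    "DKYITADV", "MDFKSNSSA", "VAWSNKSDFAC", "ANAFNNSIIPEDTFF",
    "PS", "PESSCDVKLVESF"),
  `TCR-Cb` = paste0(
    "DLENAVFPPE", "VAVFEPS", "KATLVCLATGFFPD", "HVELSWWVNGKEVH",
    "SRKLDSAL", "SENDEWTCQ", "SSRLRVSATFW", "QNPRNHFRCQVQFYG",
    "LS", "DEWTQDRAKPVTQ"),
  `TCR-Cg` = paste0(
    "DKQLYALDVS", "PKPTIFLPS", "ETKCLLEGFFPD", "VIKIHWEEKKSNTI",
    "LGRSTHQV", "EDSNGAFYM", "TSWKEDSKFNC", "NDTYMKFSWLTVPEK",
    "SL", "DKEHRCIVRHENN"),
  `TCR-Cd` = paste0(
    "SQPHTKPSVF", "VMKNGTNSA", "NVACLVEGFYPK", "DIRINLVSSKKITE",
    "FDKPSAVI", "PSGKYNTCV", "SEWHSTDFEVK", "TDSTDHVKPKETENT",
    "KQ", "PSKSDHKPKAIVH"),
  `IgA-CH3` = paste0(
    "PEEHVLLPPS", "EELALNELV", "TLTCLARGFSPK", "DVLVRWLQGSQELP",
    "EKRLWASI", "REPSQGTLT", "FALTRVAAEDW", "KKGDTFSCMVGHEAL",
    "PL", "AFTQKTIDRLAGK"),
  `IgD-CH3` = paste0(
    "PATGFSLPPS", "QPLSLEELS", "QATCLVNGHFPE", "AVNITWKQDGSNQA",
    "TGSFIPNA", "RNESGDLVH", "WLEGSQELPQA", "PWNHGETFTCTVTHP",
    "DL", "PSPQAPGRYFAHS"),
  `IgM-CH4` = paste0(
    "PDVYLLPPAR", "EQLNLRESA", "TITCLVTGFSPA", "DVFVQWMQRGQPLS",
    "YTSAPMPE", "PQAPGRYFA", "HSILTVSEEEW", "NTGETYTCVVAHEAL",
    "PN", "RVTERTVDKSTGK")
)
stopifnot(all(nchar(seqs) == 103L))

gene <- c(`IgG1-CH3` = "IGHG1", `IgG3-CH3` = "IGHG3", `TCR-Ca` = "TRAC",
          `TCR-Cb` = "TRBC1", `TCR-Cg` = "TRGC1", `TCR-Cd` = "TRDC",
          `IgA-CH3` = "IGHA1", `IgD-CH3` = "IGHD", `IgM-CH4` = "IGHM")

at <- function(class, label) {
  i <- match(label, label_scaffold)
  substr(seqs[[class]], i, i)
}

# Wild-type letters implied by the printed design material.
must <- list(
  `IgG1-CH3` = c(`3`="Q", `5`="Y", `7`="L", `13`="E", `16`="K", `20`="S",
                 `22`="T", `24`="L", `26`="K", `27`="G", `79`="K", `81`="T",
                 `84`="V", `84.2`="D", `84.4`="D", `85.1`="F", `86`="Y",
                 `88`="K", `90`="T", `115`="H", `116`="Y"),
  `TCR-Ca`   = c(`3`="Q", `5`="Y", `7`="L", `20`="K", `22`="V", `26`="T",
                 `27`="G", `79`="Y", `81`="T", `84`="V", `84.2`="D",
                 `85.1`="S", `86`="V", `88`="W", `90`="N"),
  `TCR-Cb`   = c(`3`="E", `5`="A", `7`="F", `20`="T", `22`="V", `26`="T",
                 `27`="G", `79`="K", `81`="D", `84`="L", `84.2`="E",
                 `85.1`="C", `86`="S", `88`="R", `90`="R", `84.4`="D"),
  `IgA-CH3`  = c(`3`="E", `26`="R", `81`="W", `90`="R"),
  `IgM-CH4`  = c(`115`="R", `116`="V"),
  `IgG3-CH3` = c(`115`="R", `116`="F")
)
for (cl in names(must)) {
  got <- vapply(names(must[[cl]]), function(p) at(cl, p), "")
  bad <- got != must[[cl]]
  if (any(bad)) stop(cl, ": ", paste(names(must[[cl]])[bad], "expected",
                     must[[cl]][bad], "got", got[bad], collapse = "; "))
}

# IgG3 CH3 must agree with IgG1 CH3 at every catalog interface position (the
# printed BEAT lists apply to either isotype context).
catalog <- c("3","5","7","20","22","26","27","79","81","84","84.2","85.1","86","88","90")
stopifnot(vapply(catalog, function(p) at("IgG3-CH3", p) == at("IgG1-CH3", p), NA))

# TCR Cg/Cd are curated to give the BEAT emitted-position pattern (the paper:
# same grafted-position set as BEAT, both chains hydrophobic Trp at 88).
same_a  <- c("3","5","7","27","81","84","84.2")    # Cg == IgG1
diff_a  <- c("20","22","26","79","85.1","86","90") # Cg != IgG1
stopifnot(vapply(same_a, function(p) at("TCR-Cg", p) == at("IgG1-CH3", p), NA),
          vapply(diff_a, function(p) at("TCR-Cg", p) != at("IgG1-CH3", p), NA),
          at("TCR-Cg", "88") == "W")
same_b <- c("27","79")
diff_b <- setdiff(catalog, same_b)
stopifnot(vapply(same_b, function(p) at("TCR-Cd", p) == at("IgG1-CH3", p), NA),
          vapply(diff_b, function(p) at("TCR-Cd", p) != at("IgG1-CH3", p), NA),
          at("TCR-Cd", "88") == "W")

# Homodimer donors differ from IgG1 across the half-interface partition so MI
# designs are non-trivial on both chains (IgM matches at 90 and 85.1, which the
# skip-identical rule then drops).
side1 <- c("20","79","81","88","90")
side2 <- c("3","5","26","84","84.2","85.1","86")
for (cl in c("IgA-CH3", "IgD-CH3")) {
  stopifnot(vapply(c(side1, side2),
                   function(p) at(cl, p) != at("IgG1-CH3", p), NA))
}
stopifnot(sum(vapply(c(side1, side2),
                     function(p) at("IgM-CH4", p) != at("IgG1-CH3", p), NA)) >= 9)

outdir <- file.path("inst", "extdata")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fasta <- file.path(outdir, "cdomain_references_synthetic.fasta")
con <- file(fasta, "w")
for (cl in names(seqs)) {
  writeLines(sprintf(">%s gene=%s curated=yes", cl, gene[[cl]]), con)
  writeLines(seqs[[cl]], con)
}
close(con)

tsv <- file.path(outdir, "cdomain_numbering_synthetic.tsv")
tab <- do.call(rbind, lapply(names(seqs), function(cl) {
  data.frame(domain_class = cl,
             residue_index = seq_len(103L),
             imgt_label = label_scaffold,
             residue = strsplit(seqs[[cl]], "")[[1]],
             stringsAsFactors = FALSE)
}))
write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", fasta, "and", tsv, "\n")
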