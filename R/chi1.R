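#' Dihedral angle of four points
#'
#' Signed torsion angle in degrees, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Fourth chi1 atom by residue type; NA for residues without a chi1.
chi1_gamma_atom <- function(resname) {
  switch(resname,
         GLY = NA_character_, ALA = NA_character_,
         SER = "OG", THR = "OG1", CYS = "SG",
         VAL = "CG1", ILE = "CG1",
         "CG")
}

#' Side-chain chi1 dihedral of a residue
#'
#' The N-CA-CB-gamma torsion; `NA` with attribute `reason = "no_chi1"` for
#' glycine/alanine, `NA` with `reason = "missing_atoms"` when the required
#' atoms are not resolved in the model.
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @param resno residue number.
#' @return chi1 in degrees, or `NA`.
#' @export
chi1 <- function(model, chain, resno) {
  at <- model$atoms[model$atoms$chain == chain &
                      model$atoms$resno == resno, , drop = FALSE]
  if (nrow(at) == 0) stop("residue ", chain, ":", resno,
                          " absent from model")
  g <- chi1_gamma_atom(at$resname[1])
  if (is.na(g)) {
    return(structure(NA_real_, reason = "no_chi1"))
  }
  need <- c("N", "CA", "CB", g)
  idx <- match(need, at$atom)
  if (anyNA(idx)) {
    return(structure(NA_real_, reason = "missing_atoms"))
  }
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
}

#' Side-chain orientation conservation between a graft and its donor
#'
#' Scores how many grafted positions keep their donor side-chain
#' orientation, operationalized as the chi1 dihedral agreeing within a
#' tolerance.  chi1 is an internal coordinate, so no prior superposition is
#' required.  Residues without a chi1 (Gly, Ala) count as conserved;
#' positions with unresolved atoms in either structure are excluded from
#' the denominator and reported.
#'
#' @param graft,donor IMGT-annotated [structure_model()]s.
#' @param positions IMGT positions to score.
#' @param graft_chain,donor_chain chains holding the positions.
#' @param tolerance_deg conservation tolerance on the chi1 difference
#'   (degrees).
#' @return fraction in `[0, 1]`; per-position detail in
#'   `attr(x, "detail")` and excluded positions in `attr(x, "excluded")`.
#' @export
sidechain_conservation <- function(graft, donor, positions, graft_chain,
                                   donor_chain, tolerance_deg = 60) {
  positions <- as.character(positions)
  status <- character(length(positions))
  delta <- rep(NA_real_, length(positions))
  for (k in seq_along(positions)) {
    rg <- resno_of(graft, graft_chain, positions[k])
    rd <- resno_of(donor, donor_chain, positions[k])
    if (is.na(rg) || is.na(rd)) {
      status[k] <- "excluded"
      next
    }
    cg <- chi1(graft, graft_chain, rg)
    cd <- chi1(donor, donor_chain, rd)
    if (identical(attr(cg, "reason"), "missing_atoms") ||
        identical(attr(cd, "reason"), "missing_atoms")) {
      status[k] <- "excluded"
    } else if (is.na(cg) || is.na(cd)) {
      status[k] <- "conserved"      # no chi1 to reorient
    } else {
      d <- abs(cg - cd) %% 360
      delta[k] <- min(d, 360 - d)
      status[k] <- if (delta[k] < tolerance_deg) "conserved"
      else "changed"
    }
  }
  scored <- status != "excluded"
  if (!any(scored)) stop("no position could be scored")
  frac <- sum(status[scored] == "conserved") / sum(scored)
  structure(frac,
            detail = data.frame(position = positions, status = status,
                                delta_chi1 = delta,
                                stringsAsFactors = FALSE),
            excluded = positions[!scored])
}
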