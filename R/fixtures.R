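#' Synthetic sequence and structure fixtures
#'
#' Deterministic toy inputs for exercising the analysis kernels without
#' downloading real structures: point-mutant sequences, single residues
#' with an adjustable chi1, and two-chain models whose interdomain
#' atom-atom distances are prescribed.  Geometry is idealized (canonical
#' bond lengths and angles, only the atoms the contact and chi1 criteria
#' need); the fixtures test the kernels, not chemistry.
#'
#' @name synthetic_fixtures
NULL

# Places atom x given reference points a-b-c, with |x-c| = bond, angle
# x-c-b and dihedral x-c-b-a (natural extension reference frame).
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180; dih <- -dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Side-chain topology beyond CB: atom, parents (a, b, c), bond, angle,
# dihedral ("chi1", "chi1+120", "chi1-120" or a number).
.sidechain_topology <- list(
  LYS = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CD", "CA", "CB", "CG", 1.52, 111, "180"),
             c("CE", "CB", "CG", "CD", 1.52, 111, "180"),
             c("NZ", "CG", "CD", "CE", 1.49, 111, "180")),
  ARG = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CD", "CA", "CB", "CG", 1.52, 111, "180"),
             c("NE", "CB", "CG", "CD", 1.46, 111, "180"),
             c("CZ", "CG", "CD", "NE", 1.33, 120, "180"),
             c("NH1", "CD", "NE", "CZ", 1.33, 120, "0"),
             c("NH2", "CD", "NE", "CZ", 1.33, 120, "180")),
  GLU = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CD", "CA", "CB", "CG", 1.52, 111, "180"),
             c("OE1", "CB", "CG", "CD", 1.25, 120, "0"),
             c("OE2", "CB", "CG", "CD", 1.25, 120, "180")),
  ASP = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("OD1", "CA", "CB", "CG", 1.25, 120, "0"),
             c("OD2", "CA", "CB", "CG", 1.25, 120, "180")),
  LEU = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.52, 111, "180"),
             c("CD2", "CA", "CB", "CG", 1.52, 111, "60")),
  ILE = list(c("CG1", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CG2", "N", "CA", "CB", 1.52, 111, "chi1+120"),
             c("CD1", "CA", "CB", "CG1", 1.52, 111, "180")),
  VAL = list(c("CG1", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CG2", "N", "CA", "CB", 1.52, 111, "chi1+120")),
  MET = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("SD", "CA", "CB", "CG", 1.80, 111, "180"),
             c("CE", "CB", "CG", "SD", 1.79, 100, "180")),
  PHE = list(c("CG", "N", "CA", "CB", 1.50, 114, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.39, 120, "90"),
             c("CD2", "CA", "CB", "CG", 1.39, 120, "-90")),
  TYR = list(c("CG", "N", "CA", "CB", 1.50, 114, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.39, 120, "90"),
             c("CD2", "CA", "CB", "CG", 1.39, 120, "-90")),
  TRP = list(c("CG", "N", "CA", "CB", 1.50, 114, "chi1"),
             c("CD1", "CA", "CB", "CG", 1.37, 127, "90"),
             c("CD2", "CA", "CB", "CG", 1.43, 127, "-90")),
  PRO = list(c("CG", "N", "CA", "CB", 1.49, 104, "chi1"),
             c("CD", "CA", "CB", "CG", 1.50, 105, "30")),
  ASN = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("OD1", "CA", "CB", "CG", 1.23, 120, "0"),
             c("ND2", "CA", "CB", "CG", 1.33, 120, "180")),
  GLN = list(c("CG", "N", "CA", "CB", 1.52, 111, "chi1"),
             c("CD", "CA", "CB", "CG", 1.52, 111, "180"),
             c("OE1", "CB", "CG", "CD", 1.23, 120, "0"),
             c("NE2", "CB", "CG", "CD", 1.33, 120, "180")),
  HIS = list(c("CG", "N", "CA", "CB", 1.50, 114, "chi1"),
             c("ND1", "CA", "CB", "CG", 1.38, 122, "90"),
             c("CD2", "CA", "CB", "CG", 1.36, 122, "-90"),
             c("NE2", "CB", "CG", "CD2", 1.37, 107, "180")),
  SER = list(c("OG", "N", "CA", "CB", 1.42, 111, "chi1")),
  THR = list(c("OG1", "N", "CA", "CB", 1.42, 111, "chi1"),
             c("CG2", "N", "CA", "CB", 1.52, 111, "chi1-120")),
  CYS = list(c("SG", "N", "CA", "CB", 1.81, 111, "chi1")),
  ALA = list(),
  GLY = list()
)

# Representative side-chain "tip" atom used to realize target distances.
.tip_atom <- c(LYS = "NZ", ARG = "NH1", GLU = "OE1", ASP = "OD1",
               LEU = "CD1", ILE = "CD1", VAL = "CG1", MET = "CE",
               PHE = "CD1", TYR = "CD1", TRP = "CD1", PRO = "CG",
               SER = "OG", THR = "OG1", CYS = "SG", ALA = "CB",
               ASN = "ND2", GLN = "NE2", HIS = "NE2")

#' Build one idealized residue
#'
#' @param resname three-letter residue name (see the supported set in the
#'   package source; covers the hydrophobic, basic and acidic residues plus
#'   Ser/Thr/Cys/Ala/Gly).
#' @param chi1 side-chain chi1 dihedral in degrees.
#' @param chain,resno identifiers for the emitted atoms.
#' @return atom data.frame as in [structure_model()].
#' @export
build_residue <- function(resname, chi1 = 180, chain = "A", resno = 1L) {
  resname <- toupper(resname)
  if (!resname %in% names(.sidechain_topology)) {
    stop("no idealized template for residue ", resname)
  }
  coords <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0),
    C = c(1.458 + 1.525 * cos(69 * pi / 180),
          1.525 * sin(69 * pi / 180), 0)
  )
  coords$O <- place_atom(coords$N, coords$CA, coords$C, 1.23, 120, 0)
  if (resname != "GLY") {
    coords$CB <- place_atom(coords$C, coords$N, coords$CA, 1.53, 110.5,
                            -122)
  }
  for (row in .sidechain_topology[[resname]]) {
    dih <- switch(row[7],
                  chi1 = chi1, `chi1+120` = chi1 + 120,
                  `chi1-120` = chi1 - 120, as.numeric(row[7]))
    coords[[row[1]]] <- place_atom(coords[[row[2]]], coords[[row[3]]],
                                   coords[[row[4]]], as.numeric(row[5]),
                                   as.numeric(row[6]), dih)
  }
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  data.frame(chain = chain, resno = as.integer(resno), resname = resname,
             atom = nm, element = substr(nm, 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# Proper rotation taking direction v onto +x.
rotation_to_x <- function(v) {
  v <- v / sqrt(sum(v^2))
  axis <- c(0, v[3], -v[2])                  # v x e_x
  s <- sqrt(sum(axis^2)); cth <- v[1]
  if (s < 1e-12) {
    return(if (cth > 0) diag(3) else diag(c(-1, 1, -1)))
  }
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  th <- atan2(s, cth)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

qualifying_atoms <- function(atoms, criteria) {
  sc <- side_chain_atoms(atoms, criteria)
  hyd <- sc & atoms$element == "C" &
    atoms$resname %in% criteria$hydrophobic_residues
  pos <- sc & atoms$element %in% c("N", "O") &
    atoms$resname %in% criteria$basic_residues
  neg <- sc & atoms$element == "O" &
    atoms$resname %in% criteria$acidic_residues
  hyd | pos | neg
}

#' Two-chain contact fixture with prescribed distances
#'
#' Builds a two-chain model in which each requested residue pair faces its
#' partner across the interchain axis with its minimal qualifying
#' atom-atom distance (under `criteria`) equal to the requested value
#' within 0.01 Angstrom.  Pairs are spaced far apart so they cannot
#' interact with each other.  An optional seed applies a random rigid
#' transformation to the whole model (distances unchanged); the same spec
#' and seed always produce the identical fixture.
#'
#' @param pairs list of `list(res_i =, res_j =, distance =)` with
#'   three-letter residue names.
#' @param seed optional integer; when given, a seeded random rigid motion
#'   is applied to the assembled model.
#' @param criteria see [contact_criteria()].
#' @return a [structure_model()] with chains `"A"` and `"B"`; residue `k`
#'   of each chain belongs to pair `k`.
#' @examples
#' m <- make_contact_fixture(list(list(res_i = "LYS", res_j = "GLU",
#'                                     distance = 3.5)))
#' compute_contacts(m, c("A", "B"))
#' @export
make_contact_fixture <- function(pairs, seed = NULL,
                                 criteria = contact_criteria()) {
  stopifnot(length(pairs) >= 1L)
  out <- list()
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    d <- as.numeric(p$distance)
    if (!is.finite(d) || d < 0.8) {
      stop("unrealizable pair distance: ", p$distance)
    }
    orient <- function(resname, resno, chain, sign) {
      at <- build_residue(resname, chi1 = 180, chain = chain,
                          resno = resno)
      tip <- .tip_atom[[toupper(resname)]]
      xyz <- as.matrix(at[, c("x", "y", "z")])
      v <- xyz[at$atom == tip, ] - xyz[at$atom == "CA", ]
      R <- rotation_to_x(sign * v)
      xyz <- xyz %*% t(R)      # rotate so CA->tip is along sign * x
      xyz <- sweep(xyz, 2, xyz[at$atom == tip, ])
      at[, c("x", "y", "z")] <- xyz
      at
    }
    a <- orient(p$res_i, k, "A", +1)
    b <- orient(p$res_j, k, "B", -1)
    b[, "x"] <- b[, "x"] + d
    # refine the translation so the *minimal* qualifying distance is d
    qa <- qualifying_atoms(a, criteria); qb <- qualifying_atoms(b, criteria)
    if (any(qa) && any(qb)) {
      for (it in 1:25) {
        pa <- as.matrix(a[qa, c("x", "y", "z")])
        pb <- as.matrix(b[qb, c("x", "y", "z")])
        dmin <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                           outer(pa[, 2], pb[, 2], "-")^2 +
                           outer(pa[, 3], pb[, 3], "-")^2))
        if (abs(dmin - d) < 1e-6) break
        b[, "x"] <- b[, "x"] + (d - dmin)
      }
    }
    zoff <- 40 * (k - 1)
    a$z <- a$z + zoff; b$z <- b$z + zoff
    out[[k]] <- rbind(a, b)
  }
  atoms <- do.call(rbind, out)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    R <- random_rotation()
    shift <- stats::runif(3, -20, 20)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  }
  structure_model(atoms)
}

#' Toy 3D structure of a numbered domain
#'
#' Lays the domain's residues along an extended axis (one idealized
#' residue every 6 Angstrom) so that sequence extraction, annotation and
#' superposition can be exercised on coordinates that correspond exactly
#' to a [numbered_domain()].
#'
#' @param domain a [numbered_domain()].
#' @param chain chain identifier.
#' @param offset xyz translation of the whole chain.
#' @param spacing CA-CA spacing along the axis (Angstrom).
#' @return a [structure_model()].
#' @export
make_domain_structure <- function(domain, chain = "A", offset = c(0, 0, 0),
                                  spacing = 6) {
  letters1 <- strsplit(domain$sequence, "")[[1]]
  res3 <- bio3d::aa123(letters1)
  atoms <- do.call(rbind, lapply(seq_along(res3), function(i) {
    at <- build_residue(res3[i], chi1 = 180, chain = chain, resno = i)
    at$x <- at$x + (i - 1) * spacing
    at
  }))
  atoms$x <- atoms$x + offset[1]
  atoms$y <- atoms$y + offset[2]
  atoms$z <- atoms$z + offset[3]
  structure_model(atoms)
}

#' Merge the atoms of several models
#'
#' @param ... [structure_model()]s with disjoint chain identifiers.
#' @return a single [structure_model()] (annotations are merged).
#' @export
combine_models <- function(...) {
  models <- list(...)
  out <- structure_model(do.call(rbind, lapply(models,
                                               function(m) m$atoms)))
  for (m in models) out$imgt <- c(out$imgt, m$imgt)
  out
}

#' Point-mutant sequence from a numbered reference
#'
#' @param reference a [numbered_domain()].
#' @param perturbations named character vector mapping IMGT positions to
#'   new residues, e.g. `c("20" = "K")`; empty for the unchanged sequence.
#' @return amino-acid string.
#' @examples
#' refs <- reference_set()
#' make_mutant_sequence(refs[["IgG1-CH3"]], c("20" = "K"))
#' @export
make_mutant_sequence <- function(reference, perturbations = character(0)) {
  if (length(perturbations) == 0) return(reference$sequence)
  idx <- match(names(perturbations), reference$labels)
  if (anyNA(idx)) {
    stop("unknown position(s): ",
         paste(names(perturbations)[is.na(idx)], collapse = ", "))
  }
  chars <- strsplit(reference$sequence, "")[[1]]
  chars[idx] <- toupper(perturbations)
  paste(chars, collapse = "")
}
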