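#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired coordinate sets.  The SVD solution includes a determinant
#' guard so that reflections are never returned, including for degenerate
#' (e.g. collinear) configurations.
#'
#' @param mobile,target numeric n x 3 matrices of paired coordinates.
#' @return list with `rotation` (3 x 3, applied on the right to row
#'   vectors), `translation` (length 3), `rmsd` (Angstrom) and `transform`,
#'   a function mapping an m x 3 matrix of mobile-frame coordinates into
#'   the target frame.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)) || ncol(mobile) != 3L) {
    stop("paired n x 3 coordinate matrices required")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 paired atoms are required, got ", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- P %*% R
  rmsd <- sqrt(sum((fitted - Q)^2) / n)
  translation <- ct - as.numeric(cm %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = function(x) {
         sweep(as.matrix(x) %*% R, 2, translation, "+")
       })
}

# C-alpha coordinate matrix for selected residues of a chain; rows named
# by IMGT label where the chain is annotated, else by residue number.
calpha_coords <- function(model, chain, positions = NULL) {
  at <- model$atoms
  ca <- at[at$chain == chain & at$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  labels <- imgt_of(model, chain, ca$resno)
  ids <- ifelse(is.na(labels), paste0("#", ca$resno), labels)
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ids
  if (!is.null(positions)) {
    m <- m[rownames(m) %in% as.character(positions), , drop = FALSE]
  }
  m
}

#' C-alpha superposition of two structure selections
#'
#' Pairs C-alpha atoms between corresponding chains of two models - by
#' shared IMGT position where both chains are annotated, otherwise by
#' shared residue number - and computes the least-squares rigid
#' superposition and its RMSD via [kabsch()].
#'
#' @param mobile,target [structure_model()]s.
#' @param mobile_chains,target_chains chains to pair, in corresponding
#'   order; default all shared chain identifiers.
#' @param positions optional IMGT positions (or residue numbers prefixed
#'   `"#"`) restricting the paired set.
#' @return as [kabsch()], plus `n` (number of paired atoms).
#' @export
superpose_calpha <- function(mobile, target, mobile_chains = NULL,
                             target_chains = NULL, positions = NULL) {
  if (is.matrix(mobile) && is.matrix(target)) {
    fit <- kabsch(mobile, target)
    fit$n <- nrow(mobile)
    return(fit)
  }
  mobile_chains <- mobile_chains %||%
    intersect(unique(mobile$atoms$chain), unique(target$atoms$chain))
  target_chains <- target_chains %||% mobile_chains
  stopifnot(length(mobile_chains) == length(target_chains),
            length(mobile_chains) >= 1L)
  P <- NULL; Q <- NULL
  for (k in seq_along(mobile_chains)) {
    mm <- calpha_coords(mobile, mobile_chains[k], positions)
    tt <- calpha_coords(target, target_chains[k], positions)
    shared <- intersect(rownames(mm), rownames(tt))
    P <- rbind(P, mm[shared, , drop = FALSE])
    Q <- rbind(Q, tt[shared, , drop = FALSE])
  }
  fit <- kabsch(P, Q)
  fit$n <- nrow(P)
  fit
}
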