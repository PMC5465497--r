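# Independent oracles used to cross-check the package's kernels.  These are
# deliberately naive reimplementations (dynamic programming, all-pairs
# scans, grid searches) kept apart from the code paths they validate.

# --- global alignment with unit scores (Needleman-Wunsch) -----------------
# Returns an index map: for each residue of a, the aligned residue index of
# b (NA where a aligns to a gap).
nw_align_map <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap
    )
  }
  map <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    diag_score <- S[i, j] + if (a[i] == b[j]) match else mismatch
    if (S[i + 1, j + 1] == diag_score) {
      map[i] <- j; i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  map
}

# --- brute-force interdomain contact scan ---------------------------------
# All-atom-pairs double loop applying the contact definitions directly.
brute_force_contacts <- function(model, chains, criteria = contact_criteria()) {
  chains <- sort(chains)
  at <- model$atoms
  bb <- c("N", "CA", "C", "O", "OXT")
  hyd_res <- criteria$hydrophobic_residues
  res_key <- function(r) paste(r$chain, r$resno)
  found <- list()
  a1 <- at[at$chain == chains[1], , drop = FALSE]
  a2 <- at[at$chain == chains[2], , drop = FALSE]
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
    x <- a1[i, ]; y <- a2[j, ]
    d <- sqrt((x$x - y$x)^2 + (x$y - y$y)^2 + (x$z - y$z)^2)
    kinds <- character(0)
    if (!(x$atom %in% bb) && !(y$atom %in% bb)) {
      if (x$element == "C" && y$element == "C" &&
          x$resname %in% hyd_res && y$resname %in% hyd_res &&
          d <= criteria$hydrophobic_cutoff) {
        kinds <- c(kinds, "hydrophobic")
      }
      ionic_fwd <- x$resname %in% c("LYS", "ARG", "HIS") &&
        x$element %in% c("N", "O") &&
        y$resname %in% c("ASP", "GLU") && y$element == "O"
      ionic_rev <- y$resname %in% c("LYS", "ARG", "HIS") &&
        y$element %in% c("N", "O") &&
        x$resname %in% c("ASP", "GLU") && x$element == "O"
      if ((ionic_fwd || ionic_rev) && d <= criteria$ionic_cutoff) {
        kinds <- c(kinds, "ionic")
      }
    }
    for (k in kinds) {
      id <- paste(k, x$resno, y$resno)
      if (is.null(found[[id]]) || found[[id]] > d) found[[id]] <- d
    }
  }
  if (length(found) == 0) {
    return(data.frame(kind = character(0), resno_i = integer(0),
                      resno_j = integer(0), min_distance = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(names(found), " "))
  out <- data.frame(kind = parts[, 1], resno_i = as.integer(parts[, 2]),
                    resno_j = as.integer(parts[, 3]),
                    min_distance = unname(unlist(found)),
                    stringsAsFactors = FALSE)
  out[order(out$kind, out$resno_i, out$resno_j), ]
}

# --- grid-search rigid superposition --------------------------------------
# Brute-force minimizer over rotations parameterized on an Euler-angle
# grid, refined by successive shrinking grids around the running optimum.
grid_search_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  eval_rmsd <- function(a, b, c) {
    sqrt(sum((Pc %*% t(rot(a, b, c)) - Qc)^2) / nrow(Pc))
  }
  best <- c(0, 0, 0); best_val <- Inf
  step <- pi / 12
  for (a in seq(0, 2 * pi - step, step))
    for (b in seq(0, pi, step))
      for (c in seq(0, 2 * pi - step, step)) {
        v <- eval_rmsd(a, b, c)
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  for (level in 1:10) {
    step <- step / 3
    grid <- seq(-4, 4) * step
    center <- best
    for (da in grid) for (db in grid) for (dc in grid) {
      v <- eval_rmsd(center[1] + da, center[2] + db, center[3] + dc)
      if (v < best_val) {
        best_val <- v
        best <- center + c(da, db, dc)
      }
    }
  }
  best_val
}

# --- independent polypeptide mass summation -------------------------------
# Free amino-acid average masses; chain mass = sum - (n - 1) waters.
free_aa_mass <- c(
  G = 75.07, A = 89.09, S = 105.09, P = 115.13, V = 117.15, T = 119.12,
  C = 121.16, L = 131.17, I = 131.17, N = 132.12, D = 133.10, Q = 146.15,
  K = 146.19, E = 147.13, M = 149.21, H = 155.15, F = 165.19, R = 174.20,
  Y = 181.19, W = 204.23
)
oracle_chain_mass_kda <- function(seq) {
  letters1 <- strsplit(seq, "")[[1]]
  (sum(free_aa_mass[letters1]) - (length(letters1) - 1) * 18.0153) / 1000
}
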