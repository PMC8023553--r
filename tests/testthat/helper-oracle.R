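# Independent oracles: brute-force numerical surface integration, exhaustive
# pair counting, and direct divergence evaluation. These deliberately share
# no code path with the package implementations they check.

# accessible surface area by Monte-Carlo integration: uniformly random
# points on each expanded sphere, occlusion checked against every other
# atom (no neighbour pruning, no lattice)
oracle_atom_asa <- function(atoms, probe = 1.4, n_points = 1e4, seed = 42) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  radii <- mpdimer::vdw_radii()
  r <- radii[atoms$element]
  r[is.na(r)] <- radii[[".default"]]
  re <- unname(r) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  set.seed(seed)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    g <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    p <- sweep(g * re[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dj2 <- sum((xyz[j, ] - xyz[i, ])^2)
      if (dj2 < 1e-12) { if (j < i) free[] <- FALSE; next }
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 > re[j]^2
    }
    areas[i] <- 4 * pi * re[i]^2 * mean(free)
  }
  key <- paste0(atoms$chain, ":", atoms$resi,
                ifelse(atoms$icode == "", "", atoms$icode))
  tapply(areas, factor(key, levels = unique(key)), sum)
}

# exhaustive interchain pair count per residue key (plain double loop)
oracle_pair_counts <- function(dimer, cutoff) {
  at <- dimer$atoms[dimer$atoms$element != "H", ]
  a <- at[at$chain == dimer$chain_a, ]
  b <- at[at$chain == dimer$chain_b, ]
  counts <- list()
  bump <- function(k) counts[[k]] <<- (counts[[k]] %||% 0L) + 1L
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
    if (d <= cutoff) {
      bump(paste0(a$chain[i], ":", a$resi[i]))
      bump(paste0(b$chain[j], ":", b$resi[j]))
    }
  }
  counts
}

# direct evaluation of the divergence from its three entropy terms
oracle_jsd <- function(p, f) {
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  H((p + f) / 2) - 0.5 * H(p) - 0.5 * H(f)
}

# rigid-body transform of a dimer
transform_dimer <- function(dimer, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(dimer$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, shift, "+")
  dimer$atoms$x <- xyz[, 1]; dimer$atoms$y <- xyz[, 2]
  dimer$atoms$z <- xyz[, 3]
  dimer
}

# chain-swapped view of a dimer (same atoms, roles exchanged)
swap_dimer <- function(dimer) {
  mpdimer::new_dimer(dimer$atoms, dimer$chain_b, dimer$chain_a,
                     dimer$source_id)
}

random_rotation_matrix <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res) %*% diag(sign(diag(qr.R(qr_res))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
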