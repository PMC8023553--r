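# Synthetic PDB-format structures with analytically known geometry.
#
# These fixtures stand in for downloaded membrane-protein structures: each
# motif realizes the geometric quantity a detector or the ASA engine keys on
# (donor-acceptor distance, ring dihedral, centroid separation, ...) exactly,
# so every downstream computation is testable offline.

FIXTURE_MOTIFS <- c("isolated_atom", "sphere_pair", "extended_tripeptide",
                    "hbond_pair", "salt_bridge_pair", "parallel_rings",
                    "t_rings", "cation_ring", "hydrophobic_pair",
                    "two_chain_slab")

# assemble an atom data.frame from parallel vectors
make_atoms <- function(name, resn, chain, resi, xyz, element = NULL,
                       b = NULL, occ = 1) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  if (is.null(element)) element <- infer_element(name)
  if (is.null(b)) b <- rep(10, n)
  data.frame(serial = seq_len(n), name = name, alt = "",
             resn = rep_len(resn, n), chain = rep_len(chain, n),
             resi = rep_len(resi, n), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = rep_len(occ, n), b = rep_len(b, n),
             element = element, het = FALSE, stringsAsFactors = FALSE)
}

bind_atoms <- function(...) {
  out <- do.call(rbind, list(...))
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# ideal aromatic 6-ring (PHE-like CG..CZ), bond length 1.39 A, in the
# xy-plane centered at the origin; returned in ring bond order
ring_coords <- function(radius = 1.39) {
  if (radius <= 0) stop("ring radius must be > 0")
  ang <- deg2rad(seq(0, 300, by = 60))
  cbind(radius * cos(ang), radius * sin(ang), 0)
}
RING6_NAMES <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")

phe_residue <- function(chain, resi, center, rot = diag(3), radius = 1.39) {
  xyz <- ring_coords(radius) %*% t(rot)
  xyz <- sweep(xyz, 2, center, "+")
  cb <- center + rot %*% c(-2.4, 0, 0)   # stub substituent beyond CG
  make_atoms(c(RING6_NAMES, "CB"), "PHE", chain, resi,
             rbind(xyz, as.numeric(cb)))
}

# extended zig-zag backbone; chemically idealized enough for surface work
extended_chain <- function(seqs, chain = "A", origin = c(0, 0, 0), b0 = 10) {
  rows <- list()
  for (i in seq_along(seqs)) {
    x0 <- (i - 1) * 3.9
    at <- rbind(N = c(x0, 0, 0), CA = c(x0 + 1.3, 0.5, 0),
                C = c(x0 + 2.6, 0, 0), O = c(x0 + 2.6, -1.23, 0))
    if (seqs[i] != "GLY") at <- rbind(at, CB = c(x0 + 1.3, 1.4, 1.15))
    at <- sweep(at, 2, origin, "+")
    rows[[i]] <- make_atoms(rownames(at), seqs[i], chain, i, at,
                            b = b0 + i)
  }
  do.call(bind_atoms, rows)
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(what, " must be a positive finite number")
  x
}
check_angle <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 180))
    stop(what, " must lie in [0, 180] degrees")
  x
}

#' Build a synthetic structure fixture
#'
#' Emits a small structure or dimer whose advertised geometric quantity is
#' realized exactly by the coordinates (to numerical precision), for use as
#' an offline test bed. Motifs: `isolated_atom`, `sphere_pair` (two atoms at
#' `dist`), `extended_tripeptide` (Gly-Ala-Gly), `hbond_pair` (donor-acceptor
#' at `dist` with D-H-A angle `angle`), `salt_bridge_pair` (ARG/GLU closest
#' inter-group atoms at `dist`), `parallel_rings` / `t_rings` (two PHE rings,
#' centroid separation `dist`, inter-plane angle `dihedral`), `cation_ring`
#' (LYS NZ at `dist` above a PHE ring centroid), `hydrophobic_pair`
#' (LEU CD1 / VAL CG1 at `dist`), `two_chain_slab` (two extended chains
#' separated by `separation`).
#'
#' @param motif motif name (see above).
#' @param ... motif parameters (`dist`, `angle`, `dihedral`, `offset`,
#'   `n_res`, `separation`), all distances in Angstrom, angles in degrees.
#' @param seed integer seed (only `two_chain_slab` and stochastic callers
#'   use randomness; kept for byte-identical regeneration).
#' @return an `mpd_dimer` for two-chain motifs, otherwise an
#'   `mpd_structure`.
#' @export
build_fixture <- function(motif = FIXTURE_MOTIFS, ..., seed = 1) {
  motif <- match.arg(motif)
  p <- list(...)
  with_seed(seed, switch(
    motif,
    isolated_atom = {
      new_structure(make_atoms("CA", "GLY", "A", 1, c(0, 0, 0)),
                    source_id = "fix_isolated_atom")
    },
    sphere_pair = {
      d <- check_pos(p$dist %||% 1.0, "dist")
      new_structure(make_atoms(c("CA", "CA"), "GLY", "A", c(1, 2),
                               c(0, 0, 0, d, 0, 0)),
                    source_id = "fix_sphere_pair")
    },
    extended_tripeptide = {
      new_structure(extended_chain(c("GLY", "ALA", "GLY")),
                    source_id = "fix_gag")
    },
    hbond_pair = {
      d <- check_pos(p$dist %||% 2.9, "dist")
      th <- deg2rad(check_angle(p$angle %||% 180, "angle"))
      dh <- 0.96
      h <- c(dh, 0, 0)
      u <- c(-cos(th), sin(th), 0)
      tt <- dh * cos(th) + sqrt(max(0, dh^2 * cos(th)^2 - dh^2 + d^2))
      acc <- h + tt * u
      don <- make_atoms(c("CB", "OG", "HG"), "SER", "A", 1,
                        c(-1.43, 0, 0, 0, 0, 0, h))
      # acceptor-only carbonyl so only the donor->acceptor direction exists
      aat <- make_atoms(c("C", "O"), "GLY", "B", 1,
                        c(acc + c(0.9, 0.85, 0), acc))
      new_dimer(bind_atoms(don, aat), "A", "B", "fix_hbond")
    },
    salt_bridge_pair = {
      d <- check_pos(p$dist %||% 4.0, "dist")
      arg <- make_atoms(c("CD", "NE", "CZ", "NH1", "NH2"), "ARG", "A", 1,
                        c(-0.9, -2.4, 0, 0, -1.33, 0, 0, 0, 0,
                          1.152, 0.665, 0, -1.152, 0.665, 0))
      oe1 <- c(1.152 + d, 0.665, 0)
      cd <- oe1 + c(1.0, 0.75, 0)
      oe2 <- cd + c(1.0, -0.75, 0)
      glu <- make_atoms(c("CG", "CD", "OE1", "OE2"), "GLU", "B", 1,
                        c(cd + c(0.9, 1.1, 0), cd, oe1, oe2))
      new_dimer(bind_atoms(arg, glu), "A", "B", "fix_salt_bridge")
    },
    parallel_rings = ,
    t_rings = {
      d <- check_pos(p$dist %||% if (motif == "t_rings") 5.0 else 3.6, "dist")
      dih <- check_angle(p$dihedral %||% if (motif == "t_rings") 90 else 0,
                         "dihedral")
      off <- p$offset %||% 0
      if (abs(off) >= d) stop("offset must be smaller than dist")
      h <- sqrt(d^2 - off^2)
      ra <- phe_residue("A", 1, c(0, 0, 0))
      rb <- phe_residue("B", 1, c(off, 0, h), rot = rot_x(dih))
      new_dimer(bind_atoms(ra, rb), "A", "B", paste0("fix_", motif))
    },
    cation_ring = {
      d <- check_pos(p$dist %||% 4.0, "dist")
      ring <- phe_residue("A", 1, c(0, 0, 0))
      lys <- make_atoms(c("CE", "NZ"), "LYS", "B", 1,
                        c(0, 0, d + 1.47, 0, 0, d))
      new_dimer(bind_atoms(ring, lys), "A", "B", "fix_cation_ring")
    },
    hydrophobic_pair = {
      d <- check_pos(p$dist %||% 3.8, "dist")
      leu <- make_atoms(c("CG", "CD1"), "LEU", "A", 1,
                        c(-1.53, 0, 0, 0, 0, 0))
      val <- make_atoms(c("CG1", "CB"), "VAL", "B", 1,
                        c(d, 0, 0, d + 1.53, 0, 0))
      new_dimer(bind_atoms(leu, val), "A", "B", "fix_hydrophobic")
    },
    two_chain_slab = {
      n <- p$n_res %||% 4
      sep <- check_pos(p$separation %||% 5, "separation")
      seqs <- rep_len(c("ALA", "GLY", "LEU", "SER"), n)
      a <- extended_chain(seqs, "A")
      b <- extended_chain(seqs, "B", origin = c(0, 0, sep), b0 = 20)
      new_dimer(bind_atoms(a, b), "A", "B", "fix_slab")
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a random two-chain structure
#'
#' Two self-avoiding C-alpha random walks (3.8 A steps, minimum 3.5 A
#' between non-adjacent residues) decorated with backbone and C-beta atoms
#' in randomly oriented local frames; chain B is translated along x so the
#' smallest interchain atom gap is at least `separation`. Deterministic for
#' a given seed.
#'
#' @param n_res residues per chain (>= 1).
#' @param separation minimum interchain gap in Angstrom.
#' @param seed integer seed.
#' @return an `mpd_dimer` with chains A and B.
#' @export
build_random_dimer <- function(n_res = 5, separation = 1.0, seed = 1) {
  stopifnot(n_res >= 1)
  check_pos(separation, "separation")
  with_seed(seed, {
    chain_atoms <- function(chain_id, b0) {
      ca <- matrix(0, n_res, 3)
      for (i in seq_len(n_res)[-1]) {
        for (try in 1:200) {
          u <- stats::rnorm(3); u <- u / vnorm(u)
          cand <- ca[i - 1, ] + 3.8 * u
          prev <- ca[seq_len(i - 1), , drop = FALSE]
          d <- sqrt(rowSums(sweep(prev, 2, cand)^2))
          if (all(d[-length(d)] > 3.5) || length(d) == 1) break
        }
        ca[i, ] <- cand
      }
      rows <- vector("list", n_res)
      resn <- sample(AA3, n_res, replace = TRUE)
      for (i in seq_len(n_res)) {
        rot <- random_rotation()
        loc <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0),
                     C = c(1.52, 0, 0), O = c(2.12, 1.06, 0))
        if (resn[i] != "GLY") loc <- rbind(loc, CB = c(0, 1.2, 0.95))
        xyz <- sweep(loc %*% t(rot), 2, ca[i, ], "+")
        rows[[i]] <- make_atoms(rownames(loc), resn[i], chain_id, i, xyz,
                                b = b0 + i)
      }
      do.call(bind_atoms, rows)
    }
    a <- chain_atoms("A", 10)
    b <- chain_atoms("B", 20)
    shift <- max(a$x) - min(b$x) + separation
    b$x <- b$x + shift
    new_dimer(bind_atoms(a, b), "A", "B",
              source_id = sprintf("rnd_dimer_n%d_s%d", n_res, seed))
  })
}
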