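# Accessible surface area by rolling-probe spherical point sampling and the
# derived descriptors (RSA, delta-ASA, rel-ASA).

# deterministic, near-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Accessible surface area per atom
#'
#' Shrake-Rupley-style estimate: each (heavy) atom is covered with a
#' deterministic near-uniform point lattice on its solvent-expanded sphere
#' (van der Waals radius + probe radius); points falling inside any
#' neighbouring expanded sphere are occluded, and the accessible fraction
#' scales the sphere area.
#'
#' @param x `mpd_structure`, `mpd_dimer` or atom data.frame.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points lattice points per atom (default 960).
#' @param radii named van der Waals radius table; see [vdw_radii()].
#' @param include_hydrogens if `FALSE` (default) hydrogens are excluded from
#'   the calculation entirely.
#' @param allow_default use the `.default` radius for unlisted elements
#'   (default `TRUE`); if `FALSE`, unknown elements are an error.
#' @return numeric vector of per-atom areas (A^2) aligned with the (heavy)
#'   atom rows; attribute `atoms` holds the atom table used.
#' @export
compute_asa <- function(x, probe_radius = 1.4, n_points = 960,
                        radii = vdw_radii(), include_hydrogens = FALSE,
                        allow_default = TRUE) {
  atoms <- atoms_of(x)
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms to compute ASA for")
  el <- atoms$element
  r <- unname(radii[el])
  if (anyNA(r)) {
    unknown <- unique(el[is.na(r)])
    if (allow_default && ".default" %in% names(radii)) {
      r[is.na(r)] <- radii[[".default"]]
    } else {
      stop("no van der Waals radius configured for element(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  re <- r + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i & d2[i, ] > 1e-12)
    # fully coincident duplicates: keep the surface once (first occurrence)
    dup <- which(d2[i, ] <= 1e-12 & seq_len(n) != i)
    if (any(dup < i)) { area[i] <- 0; next }
    p <- sweep(pts * re[i], 2, xyz[i, ], "+")
    if (length(nbr) == 0) {
      acc_frac <- 1
    } else {
      pd2 <- cross_dist2(p, xyz[nbr, , drop = FALSE])
      inside <- pd2 < matrix(re[nbr]^2, nrow(p), length(nbr), byrow = TRUE)
      acc_frac <- mean(rowSums(inside) == 0)
    }
    area[i] <- 4 * pi * re[i]^2 * acc_frac
  }
  attr(area, "atoms") <- atoms
  area
}

#' Accessible surface area per residue
#'
#' @inheritParams compute_asa
#' @return named numeric vector of residue ASA (A^2), names are residue keys
#'   `chain:resi[icode]`, in structure order.
#' @export
residue_asa <- function(x, probe_radius = 1.4, n_points = 960,
                        radii = vdw_radii(), include_hydrogens = FALSE,
                        allow_default = TRUE) {
  a <- compute_asa(x, probe_radius, n_points, radii, include_hydrogens,
                   allow_default)
  atoms <- attr(a, "atoms")
  key <- atom_residue_key(atoms)
  out <- tapply(a, factor(key, levels = unique(key)), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Relative solvent accessibility
#'
#' Residue ASA normalized by the residue's Gly-X-Gly reference area
#' (Sander-Rost constants). Values above 1 are possible for distorted
#' conformations and are not clamped.
#'
#' @param asa residue ASA in A^2.
#' @param residue_name three-letter code (vectorized).
#' @return RSA fraction(s).
#' @export
rsa <- function(asa, residue_name) {
  ma <- MAX_AREA[toupper(residue_name)]
  if (anyNA(ma))
    stop("no reference area for residue(s): ",
         paste(unique(residue_name[is.na(ma)]), collapse = ", "))
  out <- asa / ma
  if (any(out > 1))
    message(sprintf("%d residue(s) with RSA > 1 (distorted conformation)",
                    sum(out > 1)))
  unname(out)
}

#' Change in ASA upon complex formation and its relative form
#'
#' The change is complex-form minus monomer-form ASA (non-positive at buried
#' positions); the relative form divides by the monomer ASA. Under the
#' `buried_fraction` convention the sign is flipped and the value scaled by
#' 100, expressing the percentage of the monomer surface buried on binding.
#'
#' @param mon_asa,comp_asa monomer- and complex-form residue ASA (A^2).
#' @param convention `"literal"` (default: delta / monomer) or
#'   `"buried_fraction"` (-delta / monomer x 100).
#' @return list with numeric vectors `delta_asa` and `rel_asa`; a zero
#'   monomer area with non-zero delta yields `NA` with a warning, and 0/0
#'   is defined as 0.
#' @export
delta_and_rel_asa <- function(mon_asa, comp_asa,
                              convention = c("literal", "buried_fraction")) {
  convention <- match.arg(convention)
  stopifnot(all(mon_asa >= -1e-9), all(comp_asa >= -1e-9))
  delta <- comp_asa - mon_asa
  rel <- ifelse(mon_asa > 0, delta / mon_asa,
                ifelse(abs(delta) < 1e-9, 0, NA_real_))
  if (anyNA(rel))
    warning(sum(is.na(rel)),
            " residue(s) with zero monomer ASA but non-zero delta;",
            " rel_asa set to NA")
  if (convention == "buried_fraction") rel <- -100 * rel
  list(delta_asa = delta, rel_asa = rel)
}
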