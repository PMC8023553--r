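# Core / surface / interface classification of dimer residues.

#' Residue class from monomer RSA and interchain distance
#'
#' A residue is surface when its monomer-form RSA exceeds `rsa_cutoff`
#' (strictly; RSA equal to the cutoff is core), and a surface residue is
#' interfacial when its minimum heavy-atom distance to the partner chain is
#' strictly below `interface_cutoff`.
#'
#' @param rsa_mon monomer-form RSA (vectorized).
#' @param min_dist minimum interchain heavy-atom distance in Angstrom.
#' @param rsa_cutoff surface threshold (default 0.20).
#' @param interface_cutoff interface distance threshold in Angstrom
#'   (default 5).
#' @return character vector over `{"non_surface",
#'   "surface_non_interfacial", "surface_interfacial"}`.
#' @export
residue_class <- function(rsa_mon, min_dist, rsa_cutoff = 0.20,
                          interface_cutoff = 5) {
  ifelse(rsa_mon <= rsa_cutoff, "non_surface",
         ifelse(min_dist < interface_cutoff,
                "surface_interfacial", "surface_non_interfacial"))
}

# per-residue minimum heavy-atom distance to the partner chain
min_interchain_dist <- function(dimer, include_hydrogens = FALSE) {
  atoms <- dimer$atoms
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  a <- atoms[atoms$chain == dimer$chain_a, , drop = FALSE]
  b <- atoms[atoms$chain == dimer$chain_b, , drop = FALSE]
  d <- sqrt(cross_dist2(as.matrix(a[, c("x", "y", "z")]),
                        as.matrix(b[, c("x", "y", "z")])))
  key_a <- atom_residue_key(a)
  key_b <- atom_residue_key(b)
  min_a <- tapply(apply(d, 1, min), factor(key_a, levels = unique(key_a)), min)
  min_b <- tapply(apply(d, 2, min), factor(key_b, levels = unique(key_b)), min)
  c(stats::setNames(as.numeric(min_a), names(min_a)),
    stats::setNames(as.numeric(min_b), names(min_b)))
}

#' Classify dimer residues and compute ASA descriptors
#'
#' Computes monomer-form ASA (each chain alone) and complex-form ASA (both
#' chains together), relative accessibilities, the change on complexation
#' and its relative form, the minimum interchain heavy-atom distance, and
#' the three-way residue classification.
#'
#' @param dimer an `mpd_dimer`.
#' @param rsa_cutoff surface RSA threshold (default 0.20; strict `>`).
#' @param interface_cutoff interface distance in Angstrom (default 5;
#'   strict `<`).
#' @param probe_radius,n_points,radii passed to [compute_asa()].
#' @param rel_asa_convention passed to [delta_and_rel_asa()].
#' @return data.frame with one row per residue: `key`, `chain`, `resi`,
#'   `icode`, `resn`, `mon_asa`, `comp_asa`, `delta_asa`, `rel_asa`,
#'   `rsa_mon`, `rsa_comp`, `min_interchain_dist`, `class`.
#' @export
classify_residues <- function(dimer, rsa_cutoff = 0.20, interface_cutoff = 5,
                              probe_radius = 1.4, n_points = 960,
                              radii = vdw_radii(),
                              rel_asa_convention = "literal") {
  stopifnot(inherits(dimer, "mpd_dimer"))
  res <- residue_table(dimer)

  mon <- c(
    residue_asa(dimer$atoms[dimer$atoms$chain == dimer$chain_a, ],
                probe_radius, n_points, radii),
    residue_asa(dimer$atoms[dimer$atoms$chain == dimer$chain_b, ],
                probe_radius, n_points, radii))
  comp <- residue_asa(dimer, probe_radius, n_points, radii)
  mind <- min_interchain_dist(dimer)

  res$mon_asa <- unname(mon[res$key])
  res$comp_asa <- unname(comp[res$key])
  dr <- delta_and_rel_asa(res$mon_asa, res$comp_asa,
                          convention = rel_asa_convention)
  res$delta_asa <- dr$delta_asa
  res$rel_asa <- dr$rel_asa
  res$rsa_mon <- rsa(res$mon_asa, res$resn)
  res$rsa_comp <- rsa(res$comp_asa, res$resn)
  res$min_interchain_dist <- unname(mind[res$key])
  res$class <- residue_class(res$rsa_mon, res$min_interchain_dist,
                             rsa_cutoff, interface_cutoff)
  res
}
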