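# Detection of the seven intermolecular interaction classes between the two
# chains of a dimer: close contacts at two radii, hydrophobic contacts,
# hydrogen bonds, salt bridges, and the pi system (pi-pi stacking,
# T-stacking, cation-pi). All criteria are purely geometric; thresholds are
# BINANA-style defaults and every one is configurable.

chain_split <- function(dimer, include_hydrogens = TRUE) {
  atoms <- dimer$atoms
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  list(a = atoms[atoms$chain == dimer$chain_a, , drop = FALSE],
       b = atoms[atoms$chain == dimer$chain_b, , drop = FALSE])
}

# all interchain atom pairs with distance <= cutoff.
# method "grid" bins atoms into cutoff-sized cells and scans the 27
# neighbouring cells; "brute" evaluates the full cross-distance matrix.
# Both return identical pairs (ai, bi are row indices into a and b).
interchain_pairs <- function(a, b, cutoff, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(ai = integer(), bi = integer(), dist = numeric()))
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  if (method == "brute") {
    d <- sqrt(cross_dist2(pa, pb))
    idx <- which(d <= cutoff, arr.ind = TRUE)
    out <- data.frame(ai = idx[, 1], bi = idx[, 2], dist = d[idx])
  } else {
    cell <- function(m) floor(sweep(m, 2, c(0, 0, 0)) / cutoff)
    ca <- cell(pa); cb <- cell(pb)
    keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
    bmap <- split(seq_len(nrow(pb)), keyb)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    ai <- bi <- integer(0); dd <- numeric(0)
    for (i in seq_len(nrow(pa))) {
      nk <- paste(ca[i, 1] + offs[, 1], ca[i, 2] + offs[, 2],
                  ca[i, 3] + offs[, 3])
      cand <- unlist(bmap[nk], use.names = FALSE)
      if (is.null(cand) || length(cand) == 0) next
      d <- sqrt(colSums((t(pb[cand, , drop = FALSE]) - pa[i, ])^2))
      hit <- d <= cutoff
      if (any(hit)) {
        ai <- c(ai, rep.int(i, sum(hit)))
        bi <- c(bi, cand[hit])
        dd <- c(dd, d[hit])
      }
    }
    out <- data.frame(ai = ai, bi = bi, dist = dd)
  }
  out[order(out$ai, out$bi), , drop = FALSE]
}

# per-residue pair counts over all dimer residues (zeros kept)
count_by_residue <- function(dimer, key_a, key_b) {
  res <- residue_table(dimer)
  counts <- stats::setNames(integer(nrow(res)), res$key)
  if (length(key_a)) {
    ta <- table(c(key_a, key_b))
    counts[names(ta)] <- as.integer(ta)
  }
  counts
}

#' Interchain close contacts
#'
#' Counts interchain heavy-atom pairs within `cutoff` of each other,
#' aggregated per residue.
#'
#' @param dimer an `mpd_dimer`.
#' @param cutoff contact radius in Angstrom (the canonical radii are 2.5
#'   and 4.0).
#' @param method `"grid"` (cell-list spatial index) or `"brute"`
#'   (exhaustive); the two are exactly equivalent.
#' @param include_hydrogens include hydrogens in the pair search
#'   (default `FALSE`).
#' @return named integer vector of per-residue counts (residue keys), with
#'   attribute `pairs` holding the atom-pair table.
#' @export
close_contacts <- function(dimer, cutoff = 4.0, method = "grid",
                           include_hydrogens = FALSE) {
  cs <- chain_split(dimer, include_hydrogens)
  pr <- interchain_pairs(cs$a, cs$b, cutoff, method)
  out <- count_by_residue(dimer, atom_residue_key(cs$a)[pr$ai],
                          atom_residue_key(cs$b)[pr$bi])
  attr(out, "pairs") <- pr
  out
}

#' Interchain hydrophobic contacts
#'
#' Apolar-carbon to apolar-carbon interchain pairs within `cutoff` (an
#' apolar carbon is a side-chain carbon bonded only to carbon or hydrogen).
#'
#' @inheritParams close_contacts
#' @return named integer vector of per-residue counts.
#' @export
hydrophobic_contacts <- function(dimer, cutoff = 4.0, method = "grid") {
  cs <- chain_split(dimer, include_hydrogens = FALSE)
  a <- cs$a[is_apolar_carbon(cs$a), , drop = FALSE]
  b <- cs$b[is_apolar_carbon(cs$b), , drop = FALSE]
  pr <- interchain_pairs(a, b, cutoff, method)
  count_by_residue(dimer, atom_residue_key(a)[pr$ai],
                   atom_residue_key(b)[pr$bi])
}

empty_records <- function() {
  data.frame(kind = character(), key_a = character(), resn_a = character(),
             key_b = character(), resn_b = character(),
             distance = numeric(), angle = numeric(),
             h_present = logical(), stringsAsFactors = FALSE)
}

record_row <- function(kind, key_a, resn_a, key_b, resn_b, distance,
                       angle = NA_real_, h_present = NA) {
  data.frame(kind = kind, key_a = key_a, resn_a = resn_a, key_b = key_b,
             resn_b = resn_b, distance = distance, angle = angle,
             h_present = h_present, stringsAsFactors = FALSE)
}

# hydrogens covalently attached to a heavy atom (same residue, within bond_max)
attached_hydrogens <- function(atoms, heavy_idx, bond_max = 1.25) {
  h <- atoms[atoms$element == "H", , drop = FALSE]
  if (nrow(h) == 0) return(h[0, ])
  same <- atom_residue_key(h) == atom_residue_key(atoms)[heavy_idx]
  h <- h[same, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  d <- sqrt(colSums((t(as.matrix(h[, c("x", "y", "z")])) -
                       as.numeric(atoms[heavy_idx, c("x", "y", "z")]))^2))
  h[d <= bond_max, , drop = FALSE]
}

#' Interchain hydrogen bonds
#'
#' Donor/acceptor heavy-atom pairs across the interface within
#' `dist_cutoff`. When the donor carries an explicit hydrogen, the
#' donor-hydrogen-acceptor angle must deviate from linearity by at most
#' `angle_dev_cutoff` degrees (the most favourable hydrogen is used); when
#' no hydrogen is present the distance criterion alone applies and the
#' record is flagged (`h_present = FALSE`).
#'
#' @param dimer an `mpd_dimer`.
#' @param dist_cutoff donor-acceptor heavy-atom distance (default 4.0 A).
#' @param angle_dev_cutoff maximum deviation from a linear D-H-A arrangement
#'   in degrees (default 40).
#' @return record data.frame (one row per donor-acceptor pair) with
#'   `key_a`/`key_b` always on chains A/B of the dimer; `angle` is the
#'   D-H-A angle when measured.
#' @export
hydrogen_bonds <- function(dimer, dist_cutoff = 4.0, angle_dev_cutoff = 40) {
  atoms <- dimer$atoms
  recs <- list()
  for (don_chain in c(dimer$chain_a, dimer$chain_b)) {
    acc_chain <- setdiff(c(dimer$chain_a, dimer$chain_b), don_chain)
    don <- atoms[atoms$chain == don_chain, , drop = FALSE]
    acc <- atoms[atoms$chain == acc_chain, , drop = FALSE]
    don <- don[is_donor_atom(don), , drop = FALSE]
    acc <- acc[is_acceptor_atom(acc), , drop = FALSE]
    pr <- interchain_pairs(don, acc, dist_cutoff, "brute")
    don_atoms_all <- atoms[atoms$chain == don_chain, , drop = FALSE]
    for (k in seq_len(nrow(pr))) {
      d_row <- don[pr$ai[k], ]
      a_row <- acc[pr$bi[k], ]
      di <- which(don_atoms_all$serial == d_row$serial)
      hs <- attached_hydrogens(don_atoms_all, di)
      ang <- NA_real_
      ok <- TRUE
      if (nrow(hs) > 0) {
        angs <- vapply(seq_len(nrow(hs)), function(j) {
          hpos <- as.numeric(hs[j, c("x", "y", "z")])
          angle_between(as.numeric(d_row[c("x", "y", "z")]) - hpos,
                        as.numeric(a_row[c("x", "y", "z")]) - hpos)
        }, numeric(1))
        ang <- max(angs)
        ok <- (180 - ang) <= angle_dev_cutoff
      }
      if (!ok) next
      on_a <- don_chain == dimer$chain_a
      recs[[length(recs) + 1]] <- record_row(
        "hbond",
        key_a = if (on_a) residue_key(d_row$chain, d_row$resi, d_row$icode)
                else residue_key(a_row$chain, a_row$resi, a_row$icode),
        resn_a = if (on_a) d_row$resn else a_row$resn,
        key_b = if (on_a) residue_key(a_row$chain, a_row$resi, a_row$icode)
                else residue_key(d_row$chain, d_row$resi, d_row$icode),
        resn_b = if (on_a) a_row$resn else d_row$resn,
        distance = pr$dist[k], angle = ang, h_present = nrow(hs) > 0)
    }
  }
  if (length(recs)) do.call(rbind, recs) else empty_records()
}

# charged groups present in an atom table: list of (key, resn, atoms idx)
charged_groups <- function(atoms, defs, need_his_flag = FALSE,
                           his_charged = FALSE) {
  out <- list()
  key <- atom_residue_key(atoms)
  for (resk in unique(key)) {
    rows <- atoms[key == resk, , drop = FALSE]
    resn <- rows$resn[1]
    g <- defs[[resn]]
    if (is.null(g)) next
    if (resn == "HIS" && need_his_flag && !his_charged) next
    for (gi in g) {
      sel <- rows[rows$name %in% gi, , drop = FALSE]
      if (nrow(sel) == 0) next
      out[[length(out) + 1]] <- list(key = resk, resn = resn, atoms = sel)
    }
  }
  out
}

#' Interchain salt bridges
#'
#' Cationic group (Lys ammonium, Arg guanidinium, optionally charged His)
#' against anionic group (Asp/Glu carboxylate) across the interface; a
#' bridge is recorded when the closest inter-group atom pair lies within
#' `cutoff`. One record per residue pair.
#'
#' @param dimer an `mpd_dimer`.
#' @param cutoff closest inter-group atom distance (default 5.5 A).
#' @param his_charged treat histidine as cationic (default `FALSE`;
#'   protonation is unknowable from heavy atoms).
#' @return record data.frame; `key_a`/`key_b` on chains A/B.
#' @export
salt_bridges <- function(dimer, cutoff = 5.5, his_charged = FALSE) {
  cs <- chain_split(dimer)
  recs <- list()
  for (cat_side in c("a", "b")) {
    an_side <- if (cat_side == "a") "b" else "a"
    cats <- charged_groups(cs[[cat_side]], CATIONIC_GROUPS,
                           need_his_flag = TRUE, his_charged = his_charged)
    ans <- charged_groups(cs[[an_side]], ANIONIC_GROUPS)
    for (cg in cats) for (ag in ans) {
      d <- min_cross_dist(as.matrix(cg$atoms[, c("x", "y", "z")]),
                          as.matrix(ag$atoms[, c("x", "y", "z")]))
      if (d <= cutoff) {
        on_a <- cat_side == "a"
        recs[[length(recs) + 1]] <- record_row(
          "salt_bridge",
          key_a = if (on_a) cg$key else ag$key,
          resn_a = if (on_a) cg$resn else ag$resn,
          key_b = if (on_a) ag$key else cg$key,
          resn_b = if (on_a) ag$resn else cg$resn,
          distance = d)
      }
    }
  }
  if (length(recs)) do.call(rbind, recs) else empty_records()
}

# least-squares ring geometry: centroid, unit normal, mean radius
fit_ring <- function(xyz) {
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  normal <- normal / vnorm(normal)
  list(centroid = centroid, normal = normal,
       radius = mean(sqrt(rowSums(centered^2))),
       rms = sqrt(mean((centered %*% normal)^2)))
}

# fitted aromatic rings of an atom table
fit_rings <- function(atoms) {
  out <- list()
  key <- atom_residue_key(atoms)
  for (resk in unique(key)) {
    rows <- atoms[key == resk, , drop = FALSE]
    resn <- rows$resn[1]
    defs <- AROMATIC_RINGS[[resn]]
    if (is.null(defs)) next
    for (rn in names(defs)) {
      sel <- rows[match(defs[[rn]], rows$name), , drop = FALSE]
      if (anyNA(sel$serial)) {
        warning("ring ", rn, " of ", resk, " (", resn,
                ") has missing atoms; skipped")
        next
      }
      g <- fit_ring(as.matrix(sel[, c("x", "y", "z")]))
      out[[length(out) + 1]] <- c(list(key = resk, resn = resn, ring = rn), g)
    }
  }
  out
}

#' Interchain pi-system interactions
#'
#' Classifies aromatic ring-ring pairs across the interface as pi-pi
#' stacking (centroid distance and near-parallel planes with a lateral
#' offset inside the ring extent) or T-stacking (shorter centroid distance,
#' near-perpendicular planes), and cation-aromatic pairs as cation-pi
#' (cation group centroid close to the ring centroid and projecting inside
#' the ring). Ring pairs are assigned at most one class, pi-pi taking
#' precedence over T-stacking; one record per residue pair and kind.
#'
#' @param dimer an `mpd_dimer`.
#' @param thresholds named list with `pi_pi_dist`, `pi_pi_angle`,
#'   `t_stack_dist`, `t_stack_angle_dev`, `cation_pi_dist`, `ring_pad`
#'   (defaults 7.5 A, 30 deg, 5.0 A, 30 deg, 6.0 A, 0.75 A).
#' @param his_charged treat histidine as cationic for cation-pi.
#' @return record data.frame with kinds `pi_pi`, `t_stack`, `cation_pi`.
#' @export
pi_systems <- function(dimer, thresholds = list(), his_charged = FALSE) {
  th <- utils::modifyList(
    list(pi_pi_dist = 7.5, pi_pi_angle = 30, t_stack_dist = 5.0,
         t_stack_angle_dev = 30, cation_pi_dist = 6.0, ring_pad = 0.75),
    thresholds)
  cs <- chain_split(dimer)
  rings <- list(a = fit_rings(cs$a), b = fit_rings(cs$b))
  recs <- list()

  lateral_offset <- function(point, ring) {
    v <- point - ring$centroid
    sqrt(max(0, sum(v^2) - sum(v * ring$normal)^2))
  }

  # ring-ring: pick one class per residue pair, pi-pi before t-stack,
  # then smallest centroid distance
  best <- list()
  for (ra in rings$a) for (rb in rings$b) {
    d <- vnorm(ra$centroid - rb$centroid)
    ang <- angle_between(ra$normal, rb$normal)
    ang <- min(ang, 180 - ang)
    offset_ok <- lateral_offset(rb$centroid, ra) <= ra$radius + th$ring_pad ||
      lateral_offset(ra$centroid, rb) <= rb$radius + th$ring_pad
    kind <- if (d <= th$pi_pi_dist && ang <= th$pi_pi_angle && offset_ok)
      "pi_pi"
    else if (d <= th$t_stack_dist && abs(ang - 90) <= th$t_stack_angle_dev)
      "t_stack"
    else NA
    if (is.na(kind)) next
    pk <- paste(ra$key, rb$key)
    cand <- list(kind = kind, ra = ra, rb = rb, d = d, ang = ang)
    cur <- best[[pk]]
    if (is.null(cur) ||
        (cand$kind == "pi_pi" && cur$kind == "t_stack") ||
        (cand$kind == cur$kind && cand$d < cur$d))
      best[[pk]] <- cand
  }
  for (b in best)
    recs[[length(recs) + 1]] <- record_row(
      b$kind, b$ra$key, b$ra$resn, b$rb$key, b$rb$resn, b$d, b$ang)

  # cation-pi, both orientations
  for (cat_side in c("a", "b")) {
    ring_side <- if (cat_side == "a") "b" else "a"
    cats <- charged_groups(cs[[cat_side]], CATIONIC_GROUPS,
                           need_his_flag = TRUE, his_charged = his_charged)
    seen <- character(0)
    for (cg in cats) for (rg in rings[[ring_side]]) {
      cen <- colMeans(as.matrix(cg$atoms[, c("x", "y", "z")]))
      d <- vnorm(cen - rg$centroid)
      if (d > th$cation_pi_dist) next
      if (lateral_offset(cen, rg) > rg$radius + th$ring_pad) next
      pk <- paste(cg$key, rg$key)
      if (pk %in% seen) next
      seen <- c(seen, pk)
      on_a <- cat_side == "a"
      recs[[length(recs) + 1]] <- record_row(
        "cation_pi",
        key_a = if (on_a) cg$key else rg$key,
        resn_a = if (on_a) cg$resn else rg$resn,
        key_b = if (on_a) rg$key else cg$key,
        resn_b = if (on_a) rg$resn else cg$resn,
        distance = d)
    }
  }
  if (length(recs)) do.call(rbind, recs) else empty_records()
}

#' Per-residue interaction fingerprint
#'
#' Runs every detector over a dimer and aggregates, per residue, the counts
#' of the eight interaction kinds: close contacts at the short and long
#' radius, hydrophobic contacts, hydrogen bonds, salt bridges, pi-pi,
#' T-stacking and cation-pi.
#'
#' @param dimer an `mpd_dimer`.
#' @param config run configuration (see [validate_config()]); its
#'   `thresholds` block and `his_charged` flag drive the detectors.
#' @param method pair-search method, `"grid"` or `"brute"`.
#' @return data.frame with one row per residue (`key`, `chain`, `resi`,
#'   `icode`, `resn`, eight count columns); attribute `records` holds the
#'   long-format interaction records.
#' @export
interaction_fingerprint <- function(dimer, config = default_config(),
                                    method = "grid") {
  th <- config$thresholds
  res <- residue_table(dimer)
  res$close_25 <- as.integer(close_contacts(dimer, th$close_short, method))
  res$close_40 <- as.integer(close_contacts(dimer, th$close_long, method))
  res$hydrophobic <- as.integer(hydrophobic_contacts(dimer, th$hydrophobic,
                                                     method))
  hb <- hydrogen_bonds(dimer, th$hbond_dist, th$hbond_angle_dev)
  sb <- salt_bridges(dimer, th$salt_bridge, config$his_charged)
  pp <- pi_systems(dimer, th, config$his_charged)
  records <- rbind(hb, sb, pp)
  for (kind in c("hbond", "salt_bridge", "pi_pi", "t_stack", "cation_pi")) {
    rk <- records[records$kind == kind, , drop = FALSE]
    cnt <- stats::setNames(integer(nrow(res)), res$key)
    if (nrow(rk)) {
      ta <- table(c(rk$key_a, rk$key_b))
      cnt[names(ta)] <- as.integer(ta)
    }
    res[[kind]] <- as.integer(cnt)
  }
  attr(res, "records") <- records
  res
}
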