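test_that("close contacts respect both canonical radii", {
  d24 <- pair_dimer(2.4)
  expect_equal(sum(close_contacts(d24, 2.5)) / 2, 1)
  expect_equal(sum(close_contacts(d24, 4.0)) / 2, 1)
  d30 <- pair_dimer(3.0)
  expect_equal(sum(close_contacts(d30, 2.5)), 0)
  expect_equal(sum(close_contacts(d30, 4.0)) / 2, 1)
})

test_that("spatial-index and brute-force contact searches agree exactly", {
  for (seed in 1:8) {
    d <- build_random_dimer(7, separation = 0.6, seed = seed)
    for (cutoff in c(2.5, 4.0, 5.5)) {
      g <- close_contacts(d, cutoff, method = "grid")
      b <- close_contacts(d, cutoff, method = "brute")
      expect_identical(as.integer(g), as.integer(b))
    }
  }
})

test_that("contact counts match an exhaustive double-loop oracle", {
  for (seed in c(3, 14)) {
    d <- build_random_dimer(6, separation = 0.6, seed = seed)
    got <- close_contacts(d, 4.0)
    want <- oracle_pair_counts(d, 4.0)
    for (k in names(want))
      expect_equal(unname(got[k]), want[[k]], ignore_attr = TRUE)
    expect_equal(sum(got) / 2, sum(unlist(want)) / 2)
  }
})

test_that("hydrophobic contacts require apolar carbons on both sides", {
  hp <- build_fixture("hydrophobic_pair", dist = 3.8)
  counts <- hydrophobic_contacts(hp)
  expect_equal(unname(counts[c("A:1", "B:1")]), c(1, 1))

  # LEU CD1 against SER OG: oxygen is not an apolar carbon
  leu <- mpdimer:::make_atoms(c("CG", "CD1"), "LEU", "A", 1,
                              c(-1.5, 0, 0, 0, 0, 0))
  ser <- mpdimer:::make_atoms(c("CB", "OG"), "SER", "B", 1,
                              c(4.4, 0, 0, 3.0, 0, 0))
  d <- new_dimer(mpdimer:::bind_atoms(leu, ser), "A", "B")
  expect_equal(sum(hydrophobic_contacts(d)), 0)

  expect_identical(as.integer(hydrophobic_contacts(swap_dimer(hp))),
                   as.integer(hydrophobic_contacts(hp)))
})

test_that("hydrogen bonds apply the distance rule and the D-H-A angle rule", {
  expect_equal(nrow(hydrogen_bonds(build_fixture("hbond_pair", dist = 2.9,
                                                 angle = 180))), 1)
  expect_equal(nrow(hydrogen_bonds(build_fixture("hbond_pair", dist = 2.9,
                                                 angle = 120))), 0)
  expect_equal(nrow(hydrogen_bonds(build_fixture("hbond_pair",
                                                 dist = 4.5))), 0)
  # deviation just inside the 40-degree tolerance is kept
  rec <- hydrogen_bonds(build_fixture("hbond_pair", dist = 2.9, angle = 145))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$angle, 145, tolerance = 1e-6)
  expect_true(rec$h_present)
})

test_that("donors without explicit hydrogens fall back to distance with a flag", {
  d <- build_fixture("hbond_pair", dist = 2.9, angle = 180)
  d$atoms <- d$atoms[d$atoms$name != "HG", ]
  rec <- hydrogen_bonds(d)
  expect_equal(nrow(rec), 1)
  expect_false(rec$h_present)
  expect_true(is.na(rec$angle))
})

test_that("salt bridges use the closest inter-group atom distance", {
  pos <- salt_bridges(build_fixture("salt_bridge_pair", dist = 4.0))
  expect_equal(nrow(pos), 1)
  expect_equal(pos$kind, "salt_bridge")
  expect_equal(sort(c(pos$resn_a, pos$resn_b)), c("ARG", "GLU"))
  expect_equal(pos$distance, 4.0, tolerance = 1e-6)

  expect_equal(nrow(salt_bridges(build_fixture("salt_bridge_pair",
                                               dist = 6.5))), 0)

  # porin-like guanidinium/carboxylate geometry (synthetic reconstruction)
  expect_equal(nrow(salt_bridges(build_fixture("salt_bridge_pair",
                                               dist = 3.5))), 1)
})

test_that("histidine is cationic only when the flag says so", {
  his <- mpdimer:::make_atoms(c("CG", "ND1", "CD2", "CE1", "NE2"), "HIS",
                              "A", 1,
                              c(0, 0, 0, 1.3, 0.7, 0, 0.8, -1.2, 0,
                                2.5, 0, 0, 2.1, -1.2, 0))
  glu <- mpdimer:::make_atoms(c("CD", "OE1", "OE2"), "GLU", "B", 1,
                              c(5.6, 0.7, 0, 4.6, 0.7, 0, 6.4, 1.5, 0))
  d <- new_dimer(mpdimer:::bind_atoms(his, glu), "A", "B")
  expect_equal(nrow(salt_bridges(d, his_charged = FALSE)), 0)
  expect_equal(nrow(salt_bridges(d, his_charged = TRUE)), 1)
})

test_that("pi-system classes fire on their fixtures and not on threshold violations", {
  expect_equal(pi_systems(build_fixture("parallel_rings", dist = 3.6,
                                        dihedral = 0))$kind, "pi_pi")
  expect_equal(pi_systems(build_fixture("t_rings", dist = 5.0,
                                        dihedral = 90))$kind, "t_stack")
  expect_equal(pi_systems(build_fixture("cation_ring", dist = 4.0))$kind,
               "cation_pi")

  expect_equal(nrow(pi_systems(build_fixture("parallel_rings",
                                             dist = 8.5))), 0)
  # parallel planes tilted past 30 degrees are no longer pi-pi, and at
  # 3.6 A they are not T-stacked either
  expect_equal(nrow(pi_systems(build_fixture("parallel_rings", dist = 3.6,
                                             dihedral = 45))), 0)
  expect_equal(nrow(pi_systems(build_fixture("t_rings", dist = 5.6))), 0)
  expect_equal(nrow(pi_systems(build_fixture("cation_ring", dist = 6.8))), 0)

  # pi-pi takes precedence over T-stack for one ring pair
  tilted <- pi_systems(build_fixture("parallel_rings", dist = 3.6,
                                     dihedral = 25))
  expect_equal(tilted$kind, "pi_pi")
})

test_that("emitted records satisfy their own thresholds (self-consistency)", {
  cfg <- default_config()
  for (seed in c(2, 21)) {
    d <- build_random_dimer(8, separation = 0.6, seed = seed)
    fp <- suppressWarnings(interaction_fingerprint(d, cfg))
    rec <- attr(fp, "records")
    th <- cfg$thresholds
    lim <- c(hbond = th$hbond_dist, salt_bridge = th$salt_bridge,
             pi_pi = th$pi_pi_dist, t_stack = th$t_stack_dist,
             cation_pi = th$cation_pi_dist)
    if (nrow(rec)) {
      expect_true(all(rec$distance <= lim[rec$kind] + 1e-9))
      hb <- rec[rec$kind == "hbond" & rec$h_present, ]
      if (nrow(hb)) expect_true(all(180 - hb$angle <= th$hbond_angle_dev))
      # records always join residues on opposite chains
      expect_true(all(substr(rec$key_a, 1, 1) != substr(rec$key_b, 1, 1)))
    }
    expect_true(all(fp$close_25 <= fp$close_40))
  }
})

test_that("fingerprints are symmetric under chain swap and rigid motion", {
  cfg <- default_config()
  cols <- c("close_25", "close_40", "hydrophobic", "hbond", "salt_bridge",
            "pi_pi", "t_stack", "cation_pi")
  set.seed(99)
  for (seed in 1:6) {
    d <- build_random_dimer(6, separation = 0.7, seed = seed)
    fp <- suppressWarnings(interaction_fingerprint(d, cfg))
    sw <- suppressWarnings(interaction_fingerprint(swap_dimer(d), cfg))
    m1 <- fp[order(fp$key), cols]
    m2 <- sw[order(sw$key), cols]
    expect_identical(unname(as.matrix(m1)), unname(as.matrix(m2)))

    moved <- transform_dimer(d, random_rotation_matrix(),
                             shift = stats::rnorm(3, sd = 20))
    fm <- suppressWarnings(interaction_fingerprint(moved, cfg))
    expect_identical(unname(as.matrix(fp[cols])),
                     unname(as.matrix(fm[cols])))
  }
})

test_that("an out-of-contact dimer yields an all-zero fingerprint", {
  far <- build_fixture("two_chain_slab", n_res = 3, separation = 100)
  fp <- interaction_fingerprint(far)
  cols <- c("close_25", "close_40", "hydrophobic", "hbond", "salt_bridge",
            "pi_pi", "t_stack", "cation_pi")
  expect_true(all(as.matrix(fp[cols]) == 0))

  sb <- interaction_fingerprint(build_fixture("salt_bridge_pair"))
  expect_equal(sb$salt_bridge, c(1L, 1L))
})
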