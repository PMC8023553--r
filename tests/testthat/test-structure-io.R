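test_that("writing and re-reading a structure preserves atoms, coordinates and B-factors", {
  d <- build_fixture("two_chain_slab", n_res = 4, separation = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(d, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), nrow(d$atoms))
  expect_equal(as.matrix(s$atoms[, c("x", "y", "z")]),
               as.matrix(d$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(s$atoms$b, d$atoms$b, tolerance = 0.01)
  expect_equal(s$atoms$name, d$atoms$name)
  expect_equal(s$atoms$chain, d$atoms$chain)
})

test_that("alternate locations keep the highest-occupancy conformer, ties to 'A'", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.30 11.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.70 12.00           C",
    "ATOM      4  CB AALA A   1       2.000   1.000   0.000  0.50 13.00           C",
    "ATOM      5  CB BALA A   1       2.200   1.000   0.000  0.50 14.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 3)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(ca$x, 1.6)          # occupancy 0.70 wins
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(cb$x, 2.0)          # tie -> alt-loc 'A'
})

test_that("a file without ATOM records is an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(suppressWarnings(read_structure(f)), "empty structure|unparseable")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("sanitization maps selenomethionine to methionine and strips waters", {
  mse <- mpdimer:::make_atoms(c("N", "CA", "CB", "CG", "SE"), "MSE", "A", 1,
                              c(0, 0, 0, 1.4, 0, 0, 2, 1, 0, 3, 1, 0, 4, 2, 0))
  hoh <- mpdimer:::make_atoms("O", "HOH", "A", 90, c(9, 9, 9))
  s <- sanitize_structure(
    mpdimer:::new_structure(mpdimer:::bind_atoms(mse, hoh)))
  expect_true(all(s$atoms$resn == "MET"))
  expect_false("HOH" %in% s$atoms$resn)
  expect_true("SD" %in% s$atoms$name)
  expect_false("SE" %in% s$atoms$name)
  expect_equal(s$atoms$element[s$atoms$name == "SD"], "S")
})

test_that("sanitization leaves standard-only input unchanged and drops unknowns with a warning", {
  std <- build_fixture("two_chain_slab", n_res = 3, separation = 5)
  clean <- sanitize_structure(mpdimer:::new_structure(std$atoms))
  expect_equal(clean$atoms[, c("name", "resn", "x", "y", "z")],
               std$atoms[, c("name", "resn", "x", "y", "z")])

  odd <- mpdimer:::make_atoms(c("C1", "C2"), "XYZ", "A", 50,
                              c(0, 0, 0, 1.5, 0, 0))
  both <- mpdimer:::new_structure(mpdimer:::bind_atoms(std$atoms, odd))
  expect_warning(out <- sanitize_structure(both), "unmappable")
  expect_equal(attr(out, "n_dropped_residues"), 1L)
  expect_false("XYZ" %in% out$atoms$resn)
})

test_that("dimer enumeration respects the contact filter and pair count bound", {
  tri <- function(chains, centers) {
    do.call(mpdimer:::bind_atoms, lapply(seq_along(chains), function(i)
      mpdimer:::make_atoms("CA", "GLY", chains[i], 1, centers[[i]])))
  }
  s3 <- mpdimer:::new_structure(tri(c("A", "B", "C"),
                                    list(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.5, 0))))
  expect_length(suppressMessages(enumerate_dimers(s3, 5)), 3)

  s4 <- mpdimer:::new_structure(tri(c("A", "B", "C", "D"),
                                    list(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.5, 0),
                                         c(500, 0, 0))))
  dimers <- suppressMessages(enumerate_dimers(s4, 5))
  expect_length(dimers, 3)
  expect_false(any(vapply(dimers, function(d)
    "D" %in% c(d$chain_a, d$chain_b), logical(1))))

  s2 <- mpdimer:::new_structure(tri(c("A", "B"), list(c(0, 0, 0), c(3, 0, 0))))
  expect_length(enumerate_dimers(s2, 5), 1)
  s1 <- mpdimer:::new_structure(tri("A", list(c(0, 0, 0))))
  expect_warning(out <- enumerate_dimers(s1, 5), "single-chain")
  expect_length(out, 0)

  # every returned pair must have a genuine interchain contact (brute check)
  for (d in dimers) {
    a <- d$atoms[d$atoms$chain == d$chain_a, c("x", "y", "z")]
    b <- d$atoms[d$atoms$chain == d$chain_b, c("x", "y", "z")]
    dmin <- min(sqrt(outer(rowSums(a^2), rep(1, nrow(b))) +
                       outer(rep(1, nrow(a)), rowSums(b^2)) -
                       2 * as.matrix(a) %*% t(as.matrix(b))))
    expect_lt(dmin, 5)
  }
})

test_that("TM masking keeps annotated ranges and warns on inapplicable annotations", {
  chain <- mpdimer:::extended_chain(rep("ALA", 30), "A")
  partner <- mpdimer:::extended_chain(rep("GLY", 30), "B",
                                      origin = c(0, 0, 4.5))
  d <- new_dimer(mpdimer:::bind_atoms(chain, partner), "A", "B", "tm_test")

  ann <- data.frame(chain = c("A", "B"), start = c(10, 10), end = c(20, 20))
  masked <- apply_tm_mask(d, ann)
  expect_equal(sum(mpdimer:::residue_table(masked)$chain == "A"), 11)
  expect_equal(sort(unique(masked$atoms$resi)), 10:20)

  expect_identical(apply_tm_mask(d, NULL), d)

  off <- data.frame(chain = c("A", "B"), start = c(100, 1),
                    end = c(120, 30))
  expect_warning(kept <- apply_tm_mask(d, off), "matches no residues")
  expect_equal(nrow(kept$atoms), nrow(d$atoms))
})
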