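test_that("the worked correction-factor example gives C(LEU) = 2", {
  # 8 residues: the interface class holds 2 LEU + 2 ALA, the rest are ALA,
  # so f_class(LEU) = 0.5 and f_total(LEU) = 0.25
  classes <- c(rep("interface", 4), rep("core", 4))
  resn <- c("LEU", "LEU", "ALA", "ALA", rep("ALA", 4))
  p <- propensities(classes, resn)
  expect_equal(p$c_factor[p$class == "interface" & p$resn == "LEU"], 2.0)
})

test_that("a class distributed like the whole dataset has unit factors", {
  classes <- rep(c("x", "y"), each = 4)
  resn <- rep(c("LEU", "ALA", "GLY", "TRP"), 2)
  p <- propensities(classes, resn)
  present <- p[p$f_total > 0, ]
  expect_true(all(present$c_factor == 1))
})

test_that("factor-weighted total frequencies recover unity per class", {
  set.seed(5)
  classes <- sample(c("non_surface", "surface_non_interfacial",
                      "surface_interfacial"), 400, replace = TRUE)
  resn <- sample(names(max_area_table()), 400, replace = TRUE,
                 prob = seq(0.2, 1, length.out = 20))
  p <- propensities(classes, resn)
  for (cl in unique(p$class)) {
    sub <- p[p$class == cl & p$f_total > 0, ]
    expect_equal(sum(sub$f_total * sub$c_factor), 1, tolerance = 1e-12)
    expect_equal(sum(sub$f_class), 1, tolerance = 1e-12)
  }
})

test_that("residue types absent from the dataset have undefined factors", {
  p <- propensities(c("a", "a"), c("LEU", "ALA"))
  expect_true(is.na(p$c_factor[p$resn == "TRP"]))
  expect_false(is.na(p$c_factor[p$resn == "LEU"][1]))
  expect_error(propensities(character(0), character(0)), "empty")
})

test_that("feature correction multiplies by the factor, spares rel_asa and round-trips", {
  tab <- data.frame(class = c("a", "a", "b"), resn = c("LEU", "ALA", "LEU"),
                    close_40 = c(10, 4, 6), rel_asa = c(0.5, 0.2, 0.1))
  prop <- propensities(tab$class, tab$resn)
  cf <- prop$c_factor[match(paste(tab$class, tab$resn),
                            paste(prop$class, prop$resn))]
  out <- correct_features(tab, prop)
  expect_equal(out$close_40, tab$close_40 * cf)
  expect_equal(out$rel_asa, tab$rel_asa)
  expect_true(all(out$correction_applied))

  # dividing back restores the original values exactly
  expect_equal(out$close_40 / cf, tab$close_40, tolerance = 1e-12)

  # unit factors leave the table unchanged
  tab1 <- data.frame(class = "a", resn = c("LEU", "ALA"), v = c(3, 7))
  out1 <- correct_features(tab1, propensities(tab1$class, tab1$resn),
                           features = "v")
  expect_equal(out1$v, tab1$v)
})

test_that("summaries compute interpolated quartiles and degenerate cases", {
  tab <- data.frame(class = "a", resn = "ALA", v = c(1, 2, 3, 4))
  s <- summarize_features(tab, features = "v")
  expect_equal(s$q2, 2.5)
  expect_equal(s$avg, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
  expect_equal(s$n, 4)

  one <- summarize_features(data.frame(class = "a", resn = "GLY", v = 9),
                            features = "v")
  expect_equal(unlist(one[c("q1", "q2", "q3", "avg")]),
               c(q1 = 9, q2 = 9, q3 = 9, avg = 9))
  expect_true(is.na(one$std))
})

test_that("summary rows are ordered by increasing hydrophobicity", {
  tab <- data.frame(class = "a",
                    resn = c("ILE", "ARG", "GLY", "ILE", "ARG", "GLY"),
                    v = 1:6)
  s <- summarize_features(tab, features = "v")
  expect_equal(s$resn, c("ARG", "GLY", "ILE"))   # Arg first, Ile last
  expect_equal(kd_order(c("ILE", "ARG"))[1], "ARG")

  # permutation invariance of the summary
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(summarize_features(perm, features = "v"), s)
})

test_that("group tests cover the t-test, ANOVA and degenerate inputs", {
  tab <- data.frame(class = rep(c("a", "b"), each = 3),
                    v = c(1, 2, 3, 1, 2, 3))
  gt <- group_tests(tab, features = "v")
  tt <- gt[gt$method == "t-test", ]
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  expect_error(group_tests(data.frame(class = "a", v = 1:5),
                           features = "v"), "at least two classes")

  set.seed(7)
  big <- data.frame(class = rep(c("a", "b"), each = 100),
                    v = c(rnorm(100, 0), rnorm(100, 5)))
  gt2 <- group_tests(big, features = "v")
  p_pkg <- gt2$p_value[gt2$method == "t-test"]
  expect_lt(p_pkg, 1e-10)

  # independent standard-formula evaluation of the pooled t statistic
  x <- big$v[big$class == "a"]; y <- big$v[big$class == "b"]
  sp <- sqrt(((99) * var(x) + (99) * var(y)) / 198)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 100 + 1 / 100))
  p_manual <- 2 * pt(-abs(t_manual), df = 198)
  expect_equal(gt2$statistic[gt2$method == "t-test"], t_manual,
               tolerance = 1e-12)
  expect_equal(p_pkg, p_manual, tolerance = 1e-12)

  an <- gt2[gt2$method == "one-way ANOVA", ]
  expect_lt(an$p_value, 1e-10)
  # with two groups, F = t^2
  expect_equal(an$statistic, t_manual^2, tolerance = 1e-9)
})

test_that("the physicochemical subsets are as defined", {
  s <- residue_subsets()
  expect_setequal(s$charged, c("ASP", "GLU", "LYS", "ARG"))
  expect_setequal(s$polar, c("SER", "THR", "ASN", "GLN", "TYR", "HIS"))
  expect_setequal(s$gas, c("GLY", "ALA", "SER"))
  expect_setequal(s$excluded, c("CYS", "GLY", "PRO"))
  expect_length(s$non_polar, 7)
})
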