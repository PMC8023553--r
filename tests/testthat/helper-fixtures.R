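# shared fixture builders for the tests

# minimal two-chain dimer: one atom per chain at the given separation
pair_dimer <- function(d, resn = c("GLY", "GLY"), name = c("CA", "CA")) {
  at <- mpdimer:::make_atoms(name[1], resn[1], "A", 1, c(0, 0, 0))
  bt <- mpdimer:::make_atoms(name[2], resn[2], "B", 1, c(d, 0, 0))
  mpdimer::new_dimer(mpdimer:::bind_atoms(at, bt), "A", "B", "pair")
}

# PSI-BLAST-style ASCII PSSM text from a matrix of weighted percentages
# (rows = positions, 20 columns in A R N D C Q E G H I L K M F P S T W Y V
# order) and a residue letter per position
write_fake_pssm <- function(path, perc, residues) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = " ")))
  for (i in seq_len(nrow(perc))) {
    logodds <- paste(sprintf("%3d", rep(0L, 20)), collapse = " ")
    pc <- paste(sprintf("%3d", as.integer(perc[i, ])), collapse = " ")
    lines <- c(lines, sprintf("%5d %s  %s  %s  %.2f %.2f",
                              i, residues[i], logodds, pc, 0.5, 0.1))
  }
  writeLines(c(lines, "", "                      K         Lambda"), path)
  path
}

uniform20 <- rep(1 / 20, 20)

# random probability 20-vector (normalized gamma draws)
random_distribution <- function() {
  v <- stats::rgamma(20, shape = 0.8)
  v / sum(v)
}
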