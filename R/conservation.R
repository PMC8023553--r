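# Per-position conservation from PSSMs via Jensen-Shannon divergence
# against a selectable background amino-acid distribution.

#' Load a background amino-acid distribution
#'
#' Built-in backgrounds: `"blosum62"` (the standard published BLOSUM62
#' target frequencies, the default background of iterative sequence search),
#' and `"slim"` / `"bbtm_tm"` -- synthetic stand-in compositions for
#' alpha-helical and beta-barrel transmembrane segments respectively (the
#' published substitution-model background vectors are not redistributed
#' here; see the shipped files for provenance). A path to a 20-line
#' `name value` text file may be given instead.
#'
#' @param name background name or file path.
#' @return object of class `mpd_background`: list with `name` and `f`, a
#'   named 20-vector (one-letter codes, canonical PSSM column order)
#'   summing to 1.
#' @export
load_background <- function(name = c("blosum62", "slim", "bbtm_tm")) {
  if (length(name) == 1 && file.exists(name)) {
    path <- name
    label <- tools::file_path_sans_ext(basename(name))
  } else {
    label <- match.arg(name)
    fname <- c(blosum62 = "blosum62.txt",
               slim = "slim_tm.synthetic.txt",
               bbtm_tm = "bbtm_tm.synthetic.txt")[[label]]
    path <- system.file("extdata", "backgrounds", fname, package = "mpdimer")
    if (path == "") stop("background file missing from installation")
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("aa", "f"),
                           colClasses = c("character", "numeric"))
  f <- stats::setNames(tab$f, toupper(tab$aa))
  if (!setequal(names(f), AA1) || length(f) != 20)
    stop("background must list each of the 20 amino acids exactly once: ", path)
  if (any(f <= 0)) stop("background frequencies must be strictly positive")
  f <- f[AA1] / sum(f)
  structure(list(name = label, f = f), class = "mpd_background")
}

as_background <- function(x) {
  if (inherits(x, "mpd_background")) return(x)
  if (is.character(x)) return(load_background(x))
  if (is.numeric(x) && length(x) == 20) {
    f <- if (is.null(names(x))) stats::setNames(x, AA1) else x[AA1]
    return(structure(list(name = "custom", f = f / sum(f)),
                     class = "mpd_background"))
  }
  stop("cannot interpret background specification")
}

#' Background appropriate to a membrane-protein fold
#'
#' Alpha-helical proteins use the `slim` background and beta-barrel
#' proteins the `bbtm_tm` one.
#'
#' @param protein_fold `"alpha_helical"` or `"beta_barrel"`.
#' @return an `mpd_background`.
#' @export
appropriate_background <- function(protein_fold) {
  if (length(protein_fold) != 1 || is.na(protein_fold) ||
      !protein_fold %in% c("alpha_helical", "beta_barrel"))
    stop("unknown fold '", protein_fold,
         "': declare the fold as alpha_helical/beta_barrel ",
         "or choose a background explicitly")
  load_background(switch(protein_fold,
                         alpha_helical = "slim", beta_barrel = "bbtm_tm"))
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` layout (position, residue, 20 log-odds
#' columns, 20 weighted observed percentage columns). The percentage block
#' is divided by 100 and renormalized per position; all-zero rows are
#' replaced by the background distribution with a warning.
#'
#' @param path PSSM file path.
#' @param background background substituted into all-zero rows
#'   (name, path, vector or `mpd_background`; default `"blosum62"`).
#' @return object of class `mpd_pssm`: list with `length`, `sequence`
#'   (1-letter string) and `p`, an L x 20 matrix of per-position
#'   probabilities (columns in canonical order).
#' @export
read_pssm <- function(path, background = "blosum62") {
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 40 && all(t[1:40] %in% AA1), logical(1)))[1]
  if (is.na(hdr)) stop("not a PSI-BLAST ASCII PSSM (no amino-acid header): ",
                       path)
  aa_order <- toks[[hdr]][1:20]
  rows <- list()
  for (k in seq(hdr + 1, length(toks))) {
    t <- toks[[k]]
    if (length(t) == 0) break
    if (is.na(suppressWarnings(as.integer(t[1])))) break
    if (length(t) < 42)
      stop("malformed PSSM row at line ", k, " of ", path,
           " (expected >= 42 fields, got ", length(t), ")")
    vals <- suppressWarnings(as.numeric(t[23:42]))
    if (anyNA(vals)) stop("non-numeric PSSM percentages at line ", k,
                          " of ", path)
    rows[[length(rows) + 1]] <- list(res = t[2], p = vals)
  }
  if (length(rows) == 0) stop("PSSM contains no data rows: ", path)
  bg <- as_background(background)
  p <- t(vapply(rows, `[[`, numeric(20), "p")) / 100
  colnames(p) <- aa_order
  p <- p[, AA1, drop = FALSE]
  zero <- rowSums(p) <= 0
  if (any(zero)) {
    warning(sum(zero), " all-zero PSSM row(s) replaced by the ",
            bg$name, " background")
    p[zero, ] <- matrix(bg$f, sum(zero), 20, byrow = TRUE)
  }
  p <- p / rowSums(p)
  structure(list(length = nrow(p),
                 sequence = paste(vapply(rows, `[[`, character(1), "res"),
                                  collapse = ""),
                 p = p),
            class = "mpd_pssm")
}

# entropy in bits with 0 log 0 = 0 and a 1e-10 floor inside the log
entropy_bits <- function(v) {
  nz <- v > 0
  -sum(v[nz] * log2(pmax(v[nz], 1e-10)))
}

#' Jensen-Shannon divergence conservation score
#'
#' JSD between a position's amino-acid distribution and a background, in
#' bits (log base 2), so the score lies in [0, 1]; it is symmetric in its
#' arguments and zero exactly when the distributions coincide. Higher
#' scores mean the observed distribution departs more from the background,
#' i.e. a more conserved position.
#'
#' @param p numeric 20-vector of per-position probabilities.
#' @param background background distribution (any form accepted by
#'   [load_background()]/`as_background`, or a plain 20-vector).
#' @param tol tolerance on each distribution summing to 1.
#' @return JSD score in [0, 1].
#' @export
jsd_score <- function(p, background, tol = 1e-6) {
  f <- as_background(background)$f
  p <- as.numeric(p)
  if (length(p) != 20) stop("p must be a 20-vector")
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop("p is not a probability distribution (sum ", format(sum(p)), ")")
  m <- (p + f) / 2
  val <- entropy_bits(m) - 0.5 * entropy_bits(p) - 0.5 * entropy_bits(f)
  min(max(val, 0), 1)
}

#' Per-position conservation profile of a PSSM
#'
#' @param pssm an `mpd_pssm`.
#' @param background background specification (see [jsd_score()]).
#' @return data.frame with columns `position`, `residue`, `jsd`,
#'   `background`.
#' @export
conservation_profile <- function(pssm, background = "blosum62") {
  stopifnot(inherits(pssm, "mpd_pssm"))
  bg <- as_background(background)
  data.frame(
    position = seq_len(pssm$length),
    residue = strsplit(pssm$sequence, "")[[1]],
    jsd = apply(pssm$p, 1, jsd_score, background = bg),
    background = bg$name,
    stringsAsFactors = FALSE)
}
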