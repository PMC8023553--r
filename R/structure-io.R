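# Reading, sanitizing and slicing PDB structures into analysis-ready dimers.
#
# Atoms travel as a plain data.frame with columns:
#   serial, name, alt, resn, chain, resi, icode, x, y, z, occ, b, element
# A structure (`mpd_structure`) is that table plus a source id; a dimer
# (`mpd_dimer`) is the same restricted to two chains.

new_structure <- function(atoms, source_id = "unknown") {
  structure(list(atoms = atoms, source_id = source_id),
            class = "mpd_structure")
}

#' Construct a dimer from an atom table
#'
#' @param atoms atom data.frame (see [read_structure()]).
#' @param chain_a,chain_b the two chain identifiers (must differ).
#' @param source_id structure identifier carried into outputs.
#' @param tm_mask optional data.frame (`chain`, `resi`) of residues retained
#'   as transmembrane.
#' @return an object of class `mpd_dimer`.
#' @export
new_dimer <- function(atoms, chain_a, chain_b, source_id = "unknown",
                      tm_mask = NULL) {
  if (chain_a == chain_b) stop("dimer chains must be distinct")
  atoms <- atoms[atoms$chain %in% c(chain_a, chain_b), , drop = FALSE]
  if (!nrow(atoms[atoms$chain == chain_a, ]) || !nrow(atoms[atoms$chain == chain_b, ]))
    stop("both dimer chains must contain atoms")
  structure(list(atoms = atoms, chain_a = chain_a, chain_b = chain_b,
                 source_id = source_id, tm_mask = tm_mask),
            class = "mpd_dimer")
}

#' @export
print.mpd_structure <- function(x, ...) {
  cat(sprintf("<mpd_structure %s: %d chains, %d residues, %d atoms>\n",
              x$source_id, length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[c("chain", "resi", "icode")])),
              nrow(x$atoms)))
  invisible(x)
}

#' @export
print.mpd_dimer <- function(x, ...) {
  cat(sprintf("<mpd_dimer %s: chains %s/%s, %d residues, %d atoms>\n",
              x$source_id, x$chain_a, x$chain_b,
              nrow(unique(x$atoms[c("chain", "resi", "icode")])),
              nrow(x$atoms)))
  invisible(x)
}

atoms_of <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, c("mpd_structure", "mpd_dimer"))) return(x$atoms)
  stop("expected an atom data.frame, mpd_structure or mpd_dimer")
}

# residue key: chain:resi[icode]
residue_key <- function(chain, resi, icode = "") {
  paste0(chain, ":", resi, ifelse(is.na(icode) | icode == "", "", icode))
}

atom_residue_key <- function(atoms) residue_key(atoms$chain, atoms$resi, atoms$icode)

# one row per residue, in file order
residue_table <- function(x) {
  atoms <- atoms_of(x)
  key <- atom_residue_key(atoms)
  idx <- !duplicated(key)
  data.frame(key = key[idx], chain = atoms$chain[idx], resi = atoms$resi[idx],
             icode = atoms$icode[idx], resn = atoms$resn[idx],
             stringsAsFactors = FALSE)
}

infer_element <- function(name, elesy = NULL) {
  el <- if (is.null(elesy)) rep(NA_character_, length(name)) else toupper(trimws(elesy))
  el[!is.na(el) & el == ""] <- NA
  miss <- is.na(el)
  if (any(miss)) {
    nm <- toupper(gsub("[0-9']", "", name[miss]))
    guess <- substr(nm, 1, 1)
    guess[substr(nm, 1, 2) == "SE"] <- "SE"
    guess[substr(nm, 1, 1) == "H" | grepl("^[0-9]*H", toupper(name[miss]))] <- "H"
    el[miss] <- guess
  }
  el
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations by
#' keeping the highest-occupancy conformer (ties broken alphabetically), and
#' returns all chains of the requested model. Hydrogens are retained.
#'
#' @param path path to a PDB file.
#' @param model_index model to read from multi-model files (default 1).
#' @return an `mpd_structure`; its `atoms` element has one row per atom with
#'   columns `serial`, `name`, `alt`, `resn`, `chain`, `resi`, `icode`,
#'   `x`, `y`, `z`, `occ`, `b`, `element`, `het`.
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_index > 1,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty structure: no ATOM/HETATM records in ", path)
  if (model_index > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model ", model_index, " not present in ", path)
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resn = toupper(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resi = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = infer_element(at$elety, at$elesy),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms <- resolve_altloc(atoms)
  new_structure(atoms, source_id = sub("\\.(pdb|ent)$", "",
                                       basename(path), ignore.case = TRUE))
}

# keep, per (residue, atom name), the conformer with highest occupancy;
# ties broken by alphabetical alt-loc id
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  grp <- paste(atom_residue_key(atoms), atoms$name)
  ord <- order(grp, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  atoms$alt <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Sanitize a parsed structure
#'
#' Removes waters and heteroatom ligands, maps non-standard residues back to
#' their standard parent (e.g. selenomethionine MSE to MET, renaming SE to
#' SD), and drops residues left without heavy atoms. Residues that are
#' neither standard nor mapped are dropped with a warning.
#'
#' @param x `mpd_structure` (or atom data.frame).
#' @param mapping_table named vector mapping non-standard three-letter codes
#'   to standard ones; defaults to [nonstandard_map()].
#' @return sanitized `mpd_structure`; attribute `n_dropped_residues` counts
#'   unmappable residues removed.
#' @export
sanitize_structure <- function(x, mapping_table = nonstandard_map()) {
  atoms <- atoms_of(x)
  src <- if (inherits(x, "mpd_structure")) x$source_id else "unknown"

  atoms <- atoms[atoms$resn != "HOH" & atoms$resn != "DOD", , drop = FALSE]

  # map non-standard residues to their parent
  mapped <- atoms$resn %in% names(mapping_table)
  if (any(mapped)) {
    is_mse <- atoms$resn == "MSE" & atoms$name == "SE"
    atoms$name[is_mse] <- "SD"
    atoms$element[is_mse] <- "S"
    is_sec <- atoms$resn == "SEC" & atoms$name == "SE"
    atoms$name[is_sec] <- "SG"
    atoms$element[is_sec] <- "S"
    atoms$resn[mapped] <- unname(mapping_table[atoms$resn[mapped]])
  }

  bad <- !(atoms$resn %in% AA3)
  n_dropped <- 0L
  if (any(bad)) {
    dropped <- unique(atom_residue_key(atoms)[bad])
    n_dropped <- length(dropped)
    warning(sprintf("dropped %d residue(s) with unmappable names: %s",
                    n_dropped,
                    paste(unique(atoms$resn[bad]), collapse = ", ")))
    atoms <- atoms[!bad, , drop = FALSE]
  }
  atoms$het <- FALSE

  # drop residues with no heavy atoms
  key <- atom_residue_key(atoms)
  heavy_by_res <- tapply(atoms$element != "H", key, any)
  keep <- key %in% names(heavy_by_res)[heavy_by_res]
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL

  out <- new_structure(atoms, source_id = src)
  attr(out, "n_dropped_residues") <- n_dropped
  out
}

#' Write a structure to PDB format
#'
#' @param x `mpd_structure`, `mpd_dimer` or atom data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  atoms <- atoms_of(x)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = ifelse(atoms$het, "HETATM", "ATOM"),
    resno = atoms$resi, resid = atoms$resn, eleno = atoms$serial,
    elety = atoms$name, chain = atoms$chain,
    insert = ifelse(atoms$icode == "", NA, atoms$icode),
    o = atoms$occ, b = atoms$b, elesy = atoms$element)
  invisible(path)
}

#' Enumerate contacting chain pairs as dimers
#'
#' All unordered chain pairs of a (multi-chain) structure are formed and
#' retained when at least one interchain heavy-atom pair lies within
#' `contact_cutoff`.
#'
#' @param x sanitized `mpd_structure`.
#' @param contact_cutoff contact distance in Angstrom (default 5).
#' @return list of `mpd_dimer`; empty (with a warning) for single-chain
#'   input.
#' @export
enumerate_dimers <- function(x, contact_cutoff = 5) {
  atoms <- atoms_of(x)
  src <- if (inherits(x, "mpd_structure")) x$source_id else "unknown"
  chains <- unique(atoms$chain)
  if (length(chains) < 2) {
    warning("single-chain structure: no dimers to enumerate")
    return(list())
  }
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  out <- list()
  for (i in seq_len(length(chains) - 1)) {
    for (j in seq(i + 1, length(chains))) {
      a <- as.matrix(heavy[heavy$chain == chains[i], c("x", "y", "z")])
      b <- as.matrix(heavy[heavy$chain == chains[j], c("x", "y", "z")])
      if (min_cross_dist(a, b) < contact_cutoff) {
        out[[length(out) + 1]] <- new_dimer(atoms, chains[i], chains[j], src)
      } else {
        message(sprintf("chains %s/%s of %s: no contact within %.1f A, pair skipped",
                        chains[i], chains[j], src, contact_cutoff))
      }
    }
  }
  out
}

# minimum distance between two coordinate matrices
min_cross_dist <- function(a, b) {
  sqrt(max(0, min(cross_dist2(a, b))))
}

# squared cross-distance matrix (rows of a x rows of b)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

#' Read a transmembrane-domain annotation file
#'
#' @param path TSV with columns chain, start, end (no header), one residue
#'   range per line; multiple lines per chain allowed.
#' @return data.frame with columns `chain`, `start`, `end`.
#' @export
read_tm_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chain", "start", "end"),
                           colClasses = c("character", "integer", "integer"),
                           stringsAsFactors = FALSE)
  if (any(ann$end < ann$start)) stop("TM annotation has end < start")
  ann
}

#' Restrict a dimer to its annotated transmembrane residues
#'
#' Residues outside the annotated ranges of each chain are removed. Chains
#' absent from the annotation are kept whole with a warning; a chain whose
#' annotation matches no residues is also kept whole with a warning.
#'
#' @param dimer an `mpd_dimer`.
#' @param annotation data.frame from [read_tm_annotation()], or `NULL` to
#'   keep the dimer unchanged.
#' @return the masked `mpd_dimer` with `tm_mask` recorded.
#' @export
apply_tm_mask <- function(dimer, annotation = NULL) {
  stopifnot(inherits(dimer, "mpd_dimer"))
  if (is.null(annotation)) return(dimer)
  atoms <- dimer$atoms
  keep <- rep(TRUE, nrow(atoms))
  mask <- list()
  for (ch in c(dimer$chain_a, dimer$chain_b)) {
    rng <- annotation[annotation$chain == ch, , drop = FALSE]
    in_ch <- atoms$chain == ch
    if (nrow(rng) == 0) {
      warning("no TM annotation for chain ", ch, "; keeping all residues")
      next
    }
    ok <- rep(FALSE, nrow(atoms))
    for (k in seq_len(nrow(rng)))
      ok <- ok | (in_ch & atoms$resi >= rng$start[k] & atoms$resi <= rng$end[k])
    if (!any(ok[in_ch])) {
      warning("TM annotation for chain ", ch,
              " matches no residues; keeping chain unchanged")
      next
    }
    keep[in_ch] <- ok[in_ch]
    mask[[ch]] <- unique(atoms$resi[ok])
  }
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  new_dimer(atoms, dimer$chain_a, dimer$chain_b, dimer$source_id,
            tm_mask = if (length(mask)) mask else NULL)
}
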