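# End-to-end featurization: one dimer -> per-residue feature table and
# interaction records; a manifest of structures -> per-dimer CSVs plus
# dataset-level propensity and summary tables and a machine-readable run
# report.

# mean B-factor over a residue's heavy atoms
residue_bfactor <- function(atoms) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  key <- atom_residue_key(heavy)
  out <- tapply(heavy$b, factor(key, levels = unique(key)), mean)
  stats::setNames(as.numeric(out), names(out))
}

# attach per-residue JSD from per-chain PSSMs; positions map to residues in
# chain order, with a warning when sequence letters disagree
attach_jsd <- function(features, dimer, pssm_a, pssm_b, background) {
  features$jsd <- NA_real_
  for (side in c("a", "b")) {
    pssm <- if (side == "a") pssm_a else pssm_b
    if (is.null(pssm)) next
    ch <- if (side == "a") dimer$chain_a else dimer$chain_b
    rows <- which(features$chain == ch)
    prof <- conservation_profile(pssm, background)
    n <- min(length(rows), nrow(prof))
    if (length(rows) != nrow(prof))
      warning(sprintf("chain %s: %d residues vs %d PSSM positions; %s",
                      ch, length(rows), nrow(prof),
                      "aligning by order up to the shorter length"))
    chain_seq <- aa_three_to_one(features$resn[rows[seq_len(n)]])
    mism <- sum(chain_seq != prof$residue[seq_len(n)], na.rm = TRUE)
    if (mism > 0)
      warning(sprintf("chain %s: %d sequence mismatches against the PSSM",
                      ch, mism))
    features$jsd[rows[seq_len(n)]] <- prof$jsd[seq_len(n)]
  }
  features
}

#' Featurize one dimer
#'
#' Computes, per residue: ASA descriptors and the three-way classification,
#' mean B-factor, interaction counts for the eight kinds, and (when PSSMs
#' are given) the JSD conservation score.
#'
#' @param dimer an `mpd_dimer` (sanitized).
#' @param config configuration list (see [validate_config()]).
#' @param pssm_a,pssm_b optional `mpd_pssm` for each chain.
#' @return list with `features` (one row per residue) and `interactions`
#'   (long-format records).
#' @export
featurize_dimer <- function(dimer, config = default_config(),
                            pssm_a = NULL, pssm_b = NULL) {
  stopifnot(inherits(dimer, "mpd_dimer"))
  feats <- classify_residues(
    dimer, rsa_cutoff = config$rsa_cutoff,
    interface_cutoff = config$interface_cutoff,
    probe_radius = config$probe_radius, n_points = config$asa_points,
    rel_asa_convention = config$rel_asa_convention)
  bf <- residue_bfactor(dimer$atoms)
  feats$b_factor <- unname(bf[feats$key])
  fp <- interaction_fingerprint(dimer, config)
  feats <- merge(feats, fp[, setdiff(names(fp), c("chain", "resi", "icode",
                                                  "resn"))],
                 by = "key", sort = FALSE)
  background <- if (!is.null(config$fold))
    appropriate_background(config$fold) else config$background
  feats <- attach_jsd(feats, dimer, pssm_a, pssm_b, background)
  feats <- cbind(pdb_id = dimer$source_id, feats, stringsAsFactors = FALSE)
  list(features = feats, interactions = attr(fp, "records"))
}

#' Read a batch manifest
#'
#' @param path CSV or TSV with column `pdb_path` and optional columns
#'   `chain_a`, `chain_b`, `fold_class`, `pssm_a`, `pssm_b`, `tm_path`.
#' @return data.frame with all columns present (missing ones filled with
#'   `NA`).
#' @export
read_manifest <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  m <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  if (!"pdb_path" %in% names(m)) stop("manifest needs a pdb_path column")
  for (col in c("chain_a", "chain_b", "fold_class", "pssm_a", "pssm_b",
                "tm_path"))
    if (!col %in% names(m)) m[[col]] <- NA_character_
  m
}

non_empty <- function(x) !is.na(x) & nzchar(x)

#' Run the featurization pipeline over a manifest
#'
#' For each manifest row: read and sanitize the structure, slice out the
#' requested chain pair (or enumerate all contacting pairs when none is
#' given), apply the TM annotation if provided, featurize, and write
#' per-dimer feature and interaction CSVs. Dataset-level propensities,
#' optionally propensity-corrected features, summary statistics and a
#' machine-readable run report are written at the end. Failures are
#' isolated per row: a bad structure is logged and skipped, never aborting
#' the batch.
#'
#' @param manifest data.frame (see [read_manifest()]) or a path to one.
#' @param config configuration overrides, YAML path or `NULL`.
#' @param output_dir output directory, created if needed.
#' @return invisibly, a list with `status` (0 = complete, 2 = partial),
#'   `features`, `propensities`, `summary`, `report`.
#' @export
run_pipeline <- function(manifest, config = NULL, output_dir = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!"pdb_path" %in% names(manifest))
    stop("manifest needs a pdb_path column")
  for (col in c("chain_a", "chain_b", "fold_class", "pssm_a", "pssm_b",
                "tm_path"))
    if (!col %in% names(manifest)) manifest[[col]] <- NA_character_
  cfg <- validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  all_feats <- list()
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      if (!file.exists(row$pdb_path))
        stop("missing_file: ", row$pdb_path)
      s <- sanitize_structure(read_structure(row$pdb_path))
      dimers <- if (non_empty(row$chain_a) && non_empty(row$chain_b)) {
        list(new_dimer(s$atoms, row$chain_a, row$chain_b, s$source_id))
      } else {
        enumerate_dimers(s, cfg$contact_enumeration_cutoff)
      }
      if (length(dimers) == 0) stop("no_dimers: no contacting chain pairs")
      if (non_empty(row$tm_path)) {
        ann <- read_tm_annotation(row$tm_path)
        dimers <- lapply(dimers, apply_tm_mask, annotation = ann)
      }
      pa <- if (non_empty(row$pssm_a))
        read_pssm(row$pssm_a, cfg$background) else NULL
      pb <- if (non_empty(row$pssm_b))
        read_pssm(row$pssm_b, cfg$background) else NULL
      row_cfg <- cfg
      if (non_empty(row$fold_class)) row_cfg$fold <- row$fold_class
      out <- list()
      for (d in dimers) {
        fz <- featurize_dimer(d, row_cfg, pa, pb)
        id <- sprintf("%s_%s%s", d$source_id, d$chain_a, d$chain_b)
        utils::write.csv(fz$features,
                         file.path(output_dir, paste0(id, "_features.csv")),
                         row.names = FALSE)
        utils::write.csv(fz$interactions,
                         file.path(output_dir,
                                   paste0(id, "_interactions.csv")),
                         row.names = FALSE)
        out[[id]] <- fz$features
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1]] <- list(
        row = i, pdb_path = row$pdb_path, reason = conditionMessage(res))
      message(sprintf("row %d (%s) skipped: %s", i, row$pdb_path,
                      conditionMessage(res)))
    } else {
      all_feats <- c(all_feats, res)
    }
  }

  features <- if (length(all_feats)) do.call(rbind, all_feats) else NULL
  prop <- summary_tab <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    prop <- propensities(features$class, features$resn)
    feats_out <- if (isTRUE(cfg$correction))
      correct_features(features, prop) else features
    summary_tab <- suppressWarnings(summarize_features(feats_out))
    utils::write.csv(prop, file.path(output_dir, "propensities.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
  }

  class_counts <- if (!is.null(features))
    as.list(table(features$class)) else list()
  report <- list(
    n_dimers = length(all_feats),
    n_residues = if (is.null(features)) 0L else nrow(features),
    class_counts = class_counts,
    skipped = skipped,
    config = cfg[setdiff(names(cfg), "fold")])
  jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  status <- if (length(skipped) > 0) 2L else 0L
  invisible(list(status = status, features = features, propensities = prop,
                 summary = summary_tab, report = report))
}
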