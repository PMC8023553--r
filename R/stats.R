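# Descriptive statistics and group tests over the per-residue feature
# tables, mirroring the database's tabular summaries.

#' Order residue types by Kyte-Doolittle hydropathy
#'
#' @param resn three-letter codes.
#' @return the input ordered by increasing hydrophobicity (Arg first,
#'   Ile last).
#' @export
kd_order <- function(resn) {
  resn[order(KYTE_DOOLITTLE[toupper(resn)])]
}

#' Summary statistics of features by group
#'
#' Three quartiles (linear interpolation between order statistics), mean
#' and sample standard deviation (n - 1 denominator) for each feature,
#' split by the grouping columns. Output rows are ordered by increasing
#' Kyte-Doolittle hydropathy of the residue type; groups whose values are
#' all missing are dropped with a warning.
#'
#' @param feature_table data.frame of per-residue features.
#' @param features numeric columns to summarize; default: all numeric
#'   non-identifier columns.
#' @param group_by grouping columns (default `c("class", "resn")`).
#' @return data.frame: `feature`, grouping columns, `q1`, `q2`, `q3`,
#'   `avg`, `std`, `n`.
#' @export
summarize_features <- function(feature_table,
                               features = NULL,
                               group_by = c("class", "resn")) {
  if (is.null(features)) {
    skip <- c("resi", "rsa_mon", "rsa_comp", "min_interchain_dist")
    features <- setdiff(
      names(feature_table)[vapply(feature_table, is.numeric, logical(1))],
      skip)
  }
  stopifnot(all(group_by %in% names(feature_table)))
  grp <- interaction(feature_table[group_by], drop = TRUE, sep = "\r")
  rows <- list()
  dropped <- 0L
  for (f in features) {
    for (g in levels(grp)) {
      v <- feature_table[[f]][grp == g]
      v <- v[!is.na(v)]
      if (length(v) == 0) { dropped <- dropped + 1L; next }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      keyvals <- strsplit(g, "\r", fixed = TRUE)[[1]]
      row <- data.frame(feature = f, stringsAsFactors = FALSE)
      for (j in seq_along(group_by)) row[[group_by[j]]] <- keyvals[j]
      row$q1 <- q[1]; row$q2 <- q[2]; row$q3 <- q[3]
      row$avg <- mean(v)
      row$std <- if (length(v) > 1) stats::sd(v) else NA_real_
      row$n <- length(v)
      rows[[length(rows) + 1]] <- row
    }
  }
  if (dropped > 0) warning(dropped, " all-missing group(s) dropped")
  out <- do.call(rbind, rows)
  if (!is.null(out) && "resn" %in% names(out)) {
    hyd <- KYTE_DOOLITTLE[toupper(out$resn)]
    out <- out[order(out$feature,
                     if ("class" %in% names(out)) out$class else 0, hyd), ]
    rownames(out) <- NULL
  }
  out
}

#' Pairwise t-tests and one-way ANOVA across classes
#'
#' For each feature: two-sided independent t-tests for every class pair
#' (pooled variance by default) and a one-way ANOVA across all classes.
#' Groups with fewer than two observations yield a missing p-value with a
#' reason.
#'
#' @param feature_table data.frame of per-residue features.
#' @param features numeric feature columns (default as in
#'   [summarize_features()]).
#' @param class_col grouping column (default `"class"`).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @param p_adjust multiple-testing adjustment across comparisons within a
#'   feature: `"none"` (default, raw p-values) or any [stats::p.adjust()]
#'   method such as `"BH"`.
#' @return data.frame: `feature`, `comparison`, `method`, `statistic`,
#'   `p_value`, `note`.
#' @export
group_tests <- function(feature_table, features = NULL, class_col = "class",
                        var_equal = TRUE, p_adjust = "none") {
  if (is.null(features)) {
    skip <- c("resi", "rsa_mon", "rsa_comp", "min_interchain_dist")
    features <- setdiff(
      names(feature_table)[vapply(feature_table, is.numeric, logical(1))],
      skip)
  }
  groups <- unique(feature_table[[class_col]])
  if (length(groups) < 2)
    stop("group tests need at least two classes, got ", length(groups))
  rows <- list()
  for (f in features) {
    vals <- split(feature_table[[f]], feature_table[[class_col]])
    vals <- lapply(vals, function(v) v[!is.na(v)])
    cmb <- utils::combn(names(vals), 2)
    for (k in seq_len(ncol(cmb))) {
      g1 <- cmb[1, k]; g2 <- cmb[2, k]
      if (length(vals[[g1]]) < 2 || length(vals[[g2]]) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, comparison = paste(g1, "vs", g2), method = "t-test",
          statistic = NA_real_, p_value = NA_real_,
          note = "insufficient observations", stringsAsFactors = FALSE)
        next
      }
      tt <- tryCatch(
        stats::t.test(vals[[g1]], vals[[g2]], var.equal = var_equal),
        error = function(e) NULL)
      if (is.null(tt)) {
        # both samples constant: t is 0 / p is 1 when the means coincide
        same <- mean(vals[[g1]]) == mean(vals[[g2]])
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, comparison = paste(g1, "vs", g2), method = "t-test",
          statistic = if (same) 0 else NA_real_,
          p_value = if (same) 1 else NA_real_,
          note = "constant samples", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, comparison = paste(g1, "vs", g2), method = "t-test",
          statistic = unname(tt$statistic), p_value = tt$p.value, note = "",
          stringsAsFactors = FALSE)
      }
    }
    keep <- lengths(vals) >= 2
    if (sum(keep) >= 2) {
      df <- data.frame(v = unlist(vals[keep]),
                       g = rep(names(vals)[keep], lengths(vals[keep])))
      an <- stats::anova(stats::aov(v ~ g, data = df))
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, comparison = "anova", method = "one-way ANOVA",
        statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1], note = "",
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, comparison = "anova", method = "one-way ANOVA",
        statistic = NA_real_, p_value = NA_real_,
        note = "insufficient groups", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none")
    out$p_value <- stats::ave(out$p_value, out$feature,
                              FUN = function(p) stats::p.adjust(p, p_adjust))
  rownames(out) <- NULL
  out
}
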