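# Class-propensity correction: residue-type frequencies per class relative
# to the whole dataset, and multiplication of feature values by the
# resulting correction factor.

#' Residue-type propensities per class
#'
#' For each (class, residue type): the frequency of the residue type within
#' the class, its frequency over the whole dataset, and the correction
#' factor, their ratio. Residue types absent from the whole dataset have an
#' undefined (`NA`) factor; types present overall but absent from a class
#' have factor 0.
#'
#' @param class_labels character vector of class labels, one per residue.
#' @param residue_names matching three-letter residue codes.
#' @return data.frame with columns `class`, `resn`, `f_class`, `f_total`,
#'   `c_factor`, covering all 20 residue types per class.
#' @export
propensities <- function(class_labels, residue_names) {
  if (length(class_labels) == 0) stop("empty input")
  stopifnot(length(class_labels) == length(residue_names))
  residue_names <- toupper(residue_names)
  f_total <- as.numeric(table(factor(residue_names, levels = AA3))) /
    length(residue_names)
  classes <- sort(unique(class_labels))
  out <- do.call(rbind, lapply(classes, function(cl) {
    in_cl <- residue_names[class_labels == cl]
    f_cl <- as.numeric(table(factor(in_cl, levels = AA3))) / length(in_cl)
    data.frame(class = cl, resn = AA3, f_class = f_cl, f_total = f_total,
               c_factor = ifelse(f_total > 0, f_cl / f_total, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Multiply features by their class-propensity factor
#'
#' Each selected feature value is multiplied by the correction factor of
#' its (class, residue type). The relative-ASA column is excluded by
#' default. Rows whose factor is undefined pass through unchanged and are
#' flagged.
#'
#' @param feature_table data.frame with `class` and `resn` columns plus
#'   numeric feature columns.
#' @param prop propensity table from [propensities()] computed on the same
#'   dataset.
#' @param features character vector of columns to correct; default: all
#'   numeric columns except `rel_asa` and identifier-like columns.
#' @param exclude columns never corrected (default `"rel_asa"`).
#' @return the table with corrected features and a logical
#'   `correction_applied` column.
#' @export
correct_features <- function(feature_table, prop, features = NULL,
                             exclude = "rel_asa") {
  id_cols <- c("key", "chain", "resi", "icode", "resn", "class",
               "min_interchain_dist", "rsa_mon", "rsa_comp")
  if (is.null(features)) {
    features <- setdiff(names(feature_table)[vapply(feature_table,
                                                    is.numeric, logical(1))],
                        c(id_cols, exclude))
  } else {
    features <- setdiff(features, exclude)
  }
  idx <- match(paste(feature_table$class, feature_table$resn),
               paste(prop$class, prop$resn))
  cf <- prop$c_factor[idx]
  ok <- !is.na(cf)
  for (f in features)
    feature_table[[f]] <- ifelse(ok, feature_table[[f]] * cf,
                                 feature_table[[f]])
  feature_table$correction_applied <- ok
  feature_table
}
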