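# Tabular I/O: feature tables and annotation results.

#' Read a processed MS1 feature table from CSV
#'
#' Expected header: `feature_id,mz,rt,intensity` plus any number of
#' per-sample intensity columns named `sample_*` and an optional
#' `cluster_id` column. Empty sample cells are treated as not observed.
#'
#' @param path CSV path.
#' @param rt_unit `"seconds"` (default) or `"minutes"`; RT is converted to
#'   seconds on read.
#' @return An [ipa_features()] object.
#' @export
read_feature_table <- function(path, rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "mz", "rt", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("mz", "rt", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line %d: '%s'", col, bad[1] + 1L,
                   df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (rt_unit == "minutes") df$rt <- df$rt * 60
  sample_cols <- grep("^sample_", names(df), value = TRUE)
  ints <- if (length(sample_cols)) {
    as.matrix(df[, sample_cols, drop = FALSE])
  }
  keep <- c(req, if ("cluster_id" %in% names(df)) "cluster_id")
  ipa_features(df[, keep, drop = FALSE], intensities = ints)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]; per-sample intensities become
#' `sample_*` columns and an assigned `cluster_id` is kept.
#'
#' @param features An [ipa_features()] object.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(features, path) {
  tb <- features$table
  out <- tb[, c("feature_id", "mz", "rt", "intensity")]
  if (!all(is.na(tb$cluster_id))) out$cluster_id <- tb$cluster_id
  if (!is.null(features$intensities)) {
    ints <- features$intensities
    colnames(ints) <- paste0("sample_", seq_len(ncol(ints)))
    out <- cbind(out, ints)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an annotation table to CSV
#'
#' One row per (unit, candidate), sorted by feature then descending
#' posterior (priors when no posterior has been computed); probabilities are
#' printed with six decimals. Header comment lines (`#`) record the package
#' version and the seed when given.
#'
#' @param annot `ipa_annotations` table.
#' @param path Output CSV path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_annotations <- function(annot, path, seed = NULL) {
  key <- ifelse(is.na(annot$posterior), annot$prior, annot$posterior)
  annot <- annot[order(match(annot$feature_id, unique(annot$feature_id)),
                       -key), ]
  out <- annot[, c("feature_id", "compound_id", "name", "adduct",
                   "theoretical_mz", "ppm", "mz_score", "rt_score",
                   "iso_score", "ms2_score", "prior", "posterior")]
  fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  for (col in c("mz_score", "rt_score", "iso_score", "ms2_score",
                "prior", "posterior")) {
    out[[col]] <- fmt6(out[[col]])
  }
  out$theoretical_mz <- ifelse(is.na(out$theoretical_mz), "",
                               sprintf("%.5f", out$theoretical_mz))
  out$ppm <- ifelse(is.na(out$ppm), "", sprintf("%.3f", out$ppm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metannot %s",
                     as.character(utils::packageVersion("metannot"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back an annotation CSV written by [write_annotations()]
#'
#' @param path CSV path.
#' @return Data frame (probabilities numeric; empty cells are `NA`).
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}
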