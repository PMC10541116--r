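#' Construct a cross-link record table
#'
#' One row per cross-link spectral match (CSM): two protein accessions, two
#' 1-based residue positions, an identification score ("Max XlinkX score"
#' semantics) and an FDR in \[0, 1\]. Self-links (same protein, same residue)
#' are invalid and rejected.
#'
#' @param protein_a,protein_b character accessions.
#' @param residue_a,residue_b integer 1-based residue positions within the
#'   full-length protein sequence.
#' @param score numeric identification score, finite.
#' @param fdr numeric FDR in \[0,1\]; `NA` means "not reported" and passes
#'   the FDR filter (deposited tables are often pre-filtered).
#' @param dataset_id provenance tag (e.g. `"XL1"`, `"XL2"`).
#' @param spectral_count positive integer, defaults to 1.
#' @return A `data.frame` of class `xl_records`.
#' @export
xl_records <- function(protein_a, residue_a, protein_b, residue_b,
                       score, fdr = NA_real_, dataset_id = "XL1",
                       spectral_count = 1L) {
  n <- length(protein_a)
  fdr <- rep_len(as.numeric(fdr), n)
  dataset_id <- rep_len(as.character(dataset_id), n)
  spectral_count <- rep_len(as.integer(spectral_count), n)
  score <- rep_len(as.numeric(score), n)
  df <- data.frame(
    protein_a = as.character(protein_a),
    residue_a = as.integer(residue_a),
    protein_b = as.character(protein_b),
    residue_b = as.integer(residue_b),
    score = as.numeric(score),
    fdr = as.numeric(fdr),
    dataset_id = as.character(dataset_id),
    spectral_count = as.integer(spectral_count),
    stringsAsFactors = FALSE
  )
  validate_xl_records(df)
}

validate_xl_records <- function(df) {
  required <- c("protein_a", "residue_a", "protein_b", "residue_b",
                "score", "fdr", "dataset_id", "spectral_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("xl_records is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(df$residue_a < 1 | df$residue_b < 1))
      stop("residue positions must be >= 1")
    if (any(!is.finite(df$score)))
      stop("scores must be finite")
    self <- df$protein_a == df$protein_b & df$residue_a == df$residue_b
    if (any(self))
      stop("self-links (identical protein and residue on both sides) are invalid; first offending row: ",
           which(self)[1])
    bad_fdr <- !is.na(df$fdr) & (df$fdr < 0 | df$fdr > 1)
    if (any(bad_fdr))
      stop("fdr values must lie in [0, 1]")
  }
  class(df) <- unique(c("xl_records", class(df)))
  df
}

#' @export
print.xl_records <- function(x, ...) {
  cat("<xl_records> ", nrow(x), " cross-link record(s), ",
      length(unique(c(x$protein_a, x$protein_b))), " protein(s), dataset(s): ",
      paste(unique(x$dataset_id), collapse = ", "), "\n", sep = "")
  skipped <- attr(x, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0)
    cat("  (", nrow(skipped), " input row(s) skipped at parse time)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more row(s)\n", sep = "")
  invisible(x)
}

#' Describe the column layout of a cross-link table
#'
#' Exporters differ in their column naming; a dialect maps the semantic
#' fields onto concrete column names. `score` and `fdr` entries set to `NA`
#' mark columns absent from the file.
#'
#' @param protein_a,residue_a,protein_b,residue_b,score,fdr column names in
#'   the file.
#' @param dataset_id,spectral_count optional column names; when `NULL` the
#'   value passed to [read_xl_table()] (resp. 1) is used for all rows.
#' @return A named list of class `xl_dialect`.
#' @export
xl_dialect <- function(protein_a = "ProteinA", residue_a = "PosA",
                       protein_b = "ProteinB", residue_b = "PosB",
                       score = "Score", fdr = "FDR",
                       dataset_id = NULL, spectral_count = NULL) {
  structure(list(protein_a = protein_a, residue_a = residue_a,
                 protein_b = protein_b, residue_b = residue_b,
                 score = score, fdr = fdr,
                 dataset_id = dataset_id, spectral_count = spectral_count),
            class = "xl_dialect")
}

#' Read a cross-link identification table
#'
#' Reads CSV/TSV exports of cleavable-cross-linker workflows. Every input
#' row yields exactly one record or one logged skip (recorded in the
#' `"skipped"` attribute and reported as a warning); row order is preserved.
#' Self-links are rejected at parse time. A missing mandatory column is a
#' hard error naming the column; a missing FDR column yields `fdr = NA`
#' (passes the FDR filter) with a warning, since deposited tables may be
#' pre-filtered.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.csv` -> comma, otherwise tab) unless `sep` is given.
#' @param dialect an [xl_dialect()] describing the column layout.
#' @param dataset_id provenance tag applied to all rows when the dialect
#'   names no dataset column.
#' @param sep optional field separator override.
#' @return An `xl_records` data frame with a `"skipped"` attribute
#'   (`data.frame(row, reason)`).
#' @export
read_xl_table <- function(path, dialect = xl_dialect(), dataset_id = "XL1",
                          sep = NULL) {
  if (!file.exists(path)) stop("cross-link table not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  mandatory <- c("protein_a", "residue_a", "protein_b", "residue_b", "score")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (!(col %in% names(raw)))
      stop("mandatory column '", col, "' (", field, ") absent from ", path)
  }
  fdr_col <- dialect$fdr
  has_fdr <- !is.null(fdr_col) && !is.na(fdr_col) && fdr_col %in% names(raw)
  if (!has_fdr)
    warning("no FDR column in ", basename(path),
            "; records will pass the FDR filter by default")

  n <- nrow(raw)
  pos_a <- suppressWarnings(as.numeric(raw[[dialect$residue_a]]))
  pos_b <- suppressWarnings(as.numeric(raw[[dialect$residue_b]]))
  score <- suppressWarnings(as.numeric(raw[[dialect$score]]))
  fdr <- if (has_fdr) suppressWarnings(as.numeric(raw[[fdr_col]])) else rep(NA_real_, n)
  ds <- if (!is.null(dialect$dataset_id) && dialect$dataset_id %in% names(raw))
    as.character(raw[[dialect$dataset_id]]) else rep(dataset_id, n)
  sc <- if (!is.null(dialect$spectral_count) && dialect$spectral_count %in% names(raw))
    suppressWarnings(as.integer(raw[[dialect$spectral_count]])) else rep(1L, n)

  reason <- rep(NA_character_, n)
  bad_pos <- (is.na(pos_a) | is.na(pos_b) | pos_a < 1 | pos_b < 1 |
                pos_a != floor(pos_a) | pos_b != floor(pos_b))
  reason[bad_pos] <- "non-numeric or invalid residue position"
  bad_score <- is.na(reason) & (is.na(score) | !is.finite(score))
  reason[bad_score] <- "non-numeric score"
  pa <- as.character(raw[[dialect$protein_a]])
  pb <- as.character(raw[[dialect$protein_b]])
  selfish <- is.na(reason) & pa == pb & pos_a == pos_b
  reason[selfish] <- "self-link (same protein and residue)"
  bad_fdr <- is.na(reason) & !is.na(fdr) & (fdr < 0 | fdr > 1)
  reason[bad_fdr] <- "FDR outside [0, 1]"

  keep <- is.na(reason)
  skipped <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(skipped) > 0)
    warning("skipped ", nrow(skipped), " row(s) of ", basename(path), ": ",
            paste(sprintf("row %d (%s)", skipped$row, skipped$reason),
                  collapse = "; "))
  out <- data.frame(
    protein_a = pa[keep], residue_a = as.integer(pos_a[keep]),
    protein_b = pb[keep], residue_b = as.integer(pos_b[keep]),
    score = score[keep], fdr = fdr[keep],
    dataset_id = ds[keep], spectral_count = sc[keep],
    stringsAsFactors = FALSE
  )
  out <- validate_xl_records(out)
  attr(out, "skipped") <- skipped
  out
}

#' Write a cross-link record table
#'
#' Inverse of [read_xl_table()] for the given dialect: re-reading the file
#' reproduces the record list exactly (the tsv dialect is the lossless
#' round-trip format).
#'
#' @param records an `xl_records` data frame.
#' @param path output path; extension selects comma vs tab separation.
#' @param dialect an [xl_dialect()]; `dataset_id`/`spectral_count` columns
#'   are written as `Dataset`/`SpectralCount` when the dialect leaves them
#'   unnamed.
#' @return `path`, invisibly.
#' @export
write_xl_table <- function(records, path, dialect = xl_dialect()) {
  records <- validate_xl_records(as.data.frame(records))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(records$protein_a, records$residue_a,
                    records$protein_b, records$residue_b,
                    records$score, records$fdr,
                    records$dataset_id, records$spectral_count,
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$protein_a, dialect$residue_a,
                  dialect$protein_b, dialect$residue_b,
                  dialect$score,
                  if (is.null(dialect$fdr) || is.na(dialect$fdr)) "FDR" else dialect$fdr,
                  if (is.null(dialect$dataset_id)) "Dataset" else dialect$dataset_id,
                  if (is.null(dialect$spectral_count)) "SpectralCount" else dialect$spectral_count)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
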