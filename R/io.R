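#' @name tadpose-io
#' @title Tabular readers and writers
#'
#' @description
#' All tabular inputs are plain TSV/CSV with a header row; lines starting
#' with `#` are comments. Coordinates in TSV inputs are 1-based as printed,
#' interpreted half-open (`[start, end)`, length `end - start`). BED input
#' is 0-based half-open and converted on read so that downstream arithmetic
#' is identical. Writers emit a comment line naming the coordinate
#' convention.
NULL

coord_comment <-
  "# coordinates: 1-based start, half-open [start,end); length = end - start"

read_table_checked <- function(path, cols, sep = "\t", what = path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE)
  .assert_cols(df, cols, what)
  df
}

#' Read a gene annotation table
#'
#' TSV columns: `chrom`, `start`, `end`, `symbol`; optional `hi_pct`
#' (haploinsufficiency percentage, missing allowed and never imputed),
#' `phenotype_terms` (`;`-separated term identifiers) and
#' `expressed_in_blood` (logical). BED input (`format = "bed"`) must carry
#' chrom/start/end/name in the first four columns, 0-based half-open;
#' positions are shifted by +1 on read.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return Annotation data frame with columns `symbol`, `chrom`, `start`,
#'   `end`, `hi_pct`, `phenotype_terms`, `expressed_in_blood`.
#' @export
read_genes <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED gene input needs >= 4 columns")
    df <- data.frame(chrom = df[[1L]], start = df[[2L]] + 1, end = df[[3L]] + 1,
                     symbol = df[[4L]], stringsAsFactors = FALSE)
  } else {
    df <- read_table_checked(path, c("chrom", "start", "end", "symbol"),
                             what = "gene annotation")
  }
  if (is.null(df$hi_pct)) df$hi_pct <- NA_real_
  if (is.null(df$phenotype_terms)) df$phenotype_terms <- ""
  if (is.null(df$expressed_in_blood)) df$expressed_in_blood <- TRUE
  df$hi_pct <- as.numeric(df$hi_pct)
  df$expressed_in_blood <- as.logical(df$expressed_in_blood)
  validate_annotation(df)
}

#' Validate a gene annotation table
#'
#' @param annotation Annotation data frame.
#' @return The annotation, invisibly checked (symbols unique, intervals
#'   valid, `hi_pct` in \[0, 100\] or `NA`).
#' @export
validate_annotation <- function(annotation) {
  .assert_cols(annotation, c("symbol", "chrom", "start", "end"),
               "gene annotation")
  if (anyDuplicated(annotation$symbol))
    stop("duplicated gene symbols in annotation")
  if (any(annotation$end < annotation$start | annotation$start < 1))
    stop("invalid gene interval(s) in annotation")
  hi <- annotation$hi_pct
  if (!is.null(hi) && any(!is.na(hi) & (hi < 0 | hi > 100)))
    stop("hi_pct must lie in [0, 100] (or be missing)")
  annotation
}

#' Read a TAD map (TSV or BED)
#'
#' @inheritParams read_genes
#' @return Validated TAD data frame (`chrom`, `start`, `end`, `name`).
#' @export
read_tads <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED TAD input needs >= 3 columns")
    df <- data.frame(chrom = df[[1L]], start = df[[2L]] + 1, end = df[[3L]] + 1,
                     name = if (ncol(df) >= 4L) df[[4L]] else
                       paste0("tad", seq_len(nrow(df))),
                     stringsAsFactors = FALSE)
  } else {
    df <- read_table_checked(path, c("chrom", "start", "end"), what = "TAD map")
    if (is.null(df$name)) df$name <- paste0("tad", seq_len(nrow(df)))
  }
  validate_tad_map(df)
  df
}

#' Read a deletion table
#'
#' TSV columns: `patient_id`, `chrom`, `start`, `end`, `terminal`.
#'
#' @param path File path.
#' @return Deletion data frame (see [deletion_table()]).
#' @export
read_deletions <- function(path) {
  df <- read_table_checked(path, c("patient_id", "chrom", "start", "end",
                                   "terminal"), what = "deletion table")
  deletion_table(df$patient_id, df$chrom, df$start, df$end,
                 as.logical(df$terminal))
}

#' Read a regulatory-contact table
#'
#' TSV columns: `gene_symbol`, `chrom`, `start`, `end` — one row per
#' regulatory element contacting the named gene.
#'
#' @param path File path.
#' @return Contact data frame.
#' @export
read_contacts <- function(path) {
  read_table_checked(path, c("gene_symbol", "chrom", "start", "end"),
                     what = "contact table")
}

#' Read patient phenotype term sets
#'
#' TSV columns: `patient_id`, `terms` (`;`-separated identifiers).
#'
#' @param path File path.
#' @return Named list of character vectors, one per patient.
#' @export
read_phenotypes <- function(path) {
  df <- read_table_checked(path, c("patient_id", "terms"),
                           what = "phenotype table")
  stats::setNames(split_terms(df$terms), df$patient_id)
}

#' Read a long-format qPCR Ct table
#'
#' CSV columns: `sample_id`, `gene`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return Ct data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_table_checked(path, c("sample_id", "gene", "replicate", "ct"),
                           sep = ",", what = "Ct table")
  df$ct <- as.numeric(df$ct)
  df
}

#' Read plate endpoint data
#'
#' CSV columns: `plate_id`, `well`, `sample_id`, `role`
#' (`sample`/`control`), `replicate`, `a590`, `a750`.
#'
#' @param path File path.
#' @return Endpoint data frame.
#' @export
read_endpoints <- function(path) {
  read_table_checked(path, c("plate_id", "well", "sample_id", "role",
                             "replicate", "a590", "a750"),
                     sep = ",", what = "endpoint table")
}

#' Read empty-plate endpoint data
#'
#' CSV columns: `plate_id`, `well`, `replicate`, `a590`, `a750` (triplicate
#' per well).
#'
#' @param path File path.
#' @return Empty-plate data frame.
#' @export
read_empty_plate <- function(path) {
  read_table_checked(path, c("plate_id", "well", "replicate", "a590", "a750"),
                     sep = ",", what = "empty-plate table")
}

#' Read plate kinetic series
#'
#' CSV columns: `plate_id`, `well`, `sample_id`, `role`, `replicate`,
#' `time_min`, `od`.
#'
#' @param path File path.
#' @return Kinetics data frame.
#' @export
read_kinetics <- function(path) {
  read_table_checked(path, c("plate_id", "well", "sample_id", "role",
                             "replicate", "time_min", "od"),
                     sep = ",", what = "kinetics table")
}

#' Write a TSV with the coordinate-convention comment header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comment Comment line(s) to prepend; defaults to the coordinate
#'   convention note.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comment = coord_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CSV (no comment header, for matrix-style exports)
#'
#' @param df Data frame or matrix.
#' @param path Output path.
#' @param row_names Write row names? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_csv <- function(df, path, row_names = FALSE) {
  utils::write.csv(df, path, quote = FALSE, row.names = row_names)
  invisible(path)
}
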