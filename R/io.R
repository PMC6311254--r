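#' Read and write the pipeline's tab-separated file formats
#'
#' All tables are UTF-8 TSV with a header row; missing values are empty
#' cells, matching TCGA-style clinical exports.  Numbers are serialised at
#' full precision (R's default 15 significant digits) so a write/read
#' round-trip reproduces in-memory values exactly.
#'
#' @name pipeline-io
#' @keywords internal
NULL

CLINICAL_COLUMNS <- c("submitter_id", "vital_status",
                      "days_to_death", "days_to_last_follow_up")

#' Read an expression matrix from TSV
#'
#' Expected layout: header row, first column sample IDs, remaining columns
#' one transcript each; values nonnegative expression quantities.
#'
#' @param path TSV file path.
#' @return Numeric matrix, samples x transcripts, with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_input("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop_input("expression file has no columns: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (anyNA(m))
    stop_input("expression file contains missing values: ", path)
  if (any(!is.finite(m)) || any(m < 0))
    stop_input("expression values must be finite and >= 0: ", path)
  m
}

#' @rdname read_expression
#' @param mat samples x transcripts numeric matrix with dimnames.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))   # 17 digits: exact round-trip
  df <- data.frame(sample_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a clinical table in TCGA export dialect
#'
#' Requires the columns \code{submitter_id}, \code{vital_status},
#' \code{days_to_death}, \code{days_to_last_follow_up}; blank cells are
#' missing values.
#'
#' @param path TSV file path.
#' @return Data frame with the four clinical columns (times numeric,
#'   missing as \code{NA}).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_input("clinical file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing))
    stop_input("clinical table ", path, " lacks required column(s): ",
               paste(missing, collapse = ", "))
  df <- df[, CLINICAL_COLUMNS]
  df$submitter_id <- as.character(df$submitter_id)
  df$days_to_death <- as.numeric(df$days_to_death)
  df$days_to_last_follow_up <- as.numeric(df$days_to_last_follow_up)
  df
}

#' @rdname read_clinical
#' @param clinical clinical data frame.
#' @export
write_clinical <- function(clinical, path) {
  stopifnot(all(CLINICAL_COLUMNS %in% names(clinical)))
  utils::write.table(clinical[, CLINICAL_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read known lncRNA-disease association pairs
#'
#' Two-column TSV: lncRNA ID, disease ID (header optional; detected by
#' checking whether the first row matches \code{lncrna\tdisease}).
#'
#' @param path TSV file path.
#' @return Data frame with columns \code{lncrna}, \code{disease}.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop_input("association file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- identical(tolower(strsplit(first, "\t")[[1L]][1:2]),
                      c("lncrna", "disease"))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("association file needs two columns: ", path)
  df <- df[, 1:2]
  names(df) <- c("lncrna", "disease")
  df$lncrna <- as.character(df$lncrna)
  df$disease <- as.character(df$disease)
  if (anyDuplicated(df)) stop_input("duplicate association pairs in ", path)
  df
}

#' Write a candidate ranking to TSV
#'
#' @param ranking a \code{candidate_ranking} (see [differential_screen()]).
#' @param path output TSV path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(transcript_id = ranking$transcript_ids,
                   p_value = ranking$p_values,
                   rank = seq_along(ranking$transcript_ids))
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop_input("ranking file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_ranking(as.character(df$transcript_id), as.numeric(df$p_value))
}
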