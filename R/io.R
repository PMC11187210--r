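# Delimited-table I/O. All artifacts are plain text: numeric matrices with
# features as rows and samples as columns, metadata and regulon tables as
# TSV, reports as JSON.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a features x samples numeric matrix from a delimited file
#'
#' The first column holds feature identifiers; the delimiter (tab or
#' comma) is auto-detected from the header line. Duplicate identifiers
#' and ragged rows are rejected.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix body of ", path)
  rownames(m) <- ids
  m
}

#' Write a features x samples matrix as TSV
#'
#' @param matrix numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name for the identifier column (default "feature_id").
#' @export
write_matrix <- function(matrix, path, id_col = "feature_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Expects columns `sample_id`, `condition_id`, and optionally
#' `replicate`, `batch`, `is_reference` (filled with defaults if absent).
#'
#' @param path file path (TSV or CSV, auto-detected).
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "condition_id")
  missing <- setdiff(required, names(md))
  if (length(missing)) stop("metadata lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (is.null(md$batch)) md$batch <- "batch1"
  if (is.null(md$replicate)) md$replicate <- 1L
  if (is.null(md$is_reference)) md$is_reference <- FALSE
  md$is_reference <- as.logical(md$is_reference)
  md
}

#' Read a regulon database (regulator, gene) table
#'
#' @param path two-column delimited file with header `regulator`, `gene`.
#' @return named list mapping each regulator to its gene set.
#' @export
read_regulon_db <- function(path) {
  db <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  if (!all(c("regulator", "gene") %in% names(db))) {
    stop("regulon table needs columns 'regulator' and 'gene'")
  }
  lapply(split(db$gene, db$regulator), unique)
}

#' Write an analysis report as JSON
#'
#' @param x list to serialize.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
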