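# Tabular readers/writers for the pipeline's plain-text formats.
#
# Expression matrices are plain numeric matrices, features in rows and
# samples in columns, with unique rownames (feature ids) and colnames
# (sample ids). `NA` is the only missing-value sentinel; downstream
# computation stages reject missing values rather than silently drop them.

#' Read an expression matrix from tab-separated text
#'
#' The expected layout is a header row of sample identifiers, then one row
#' per feature with the feature identifier in the first column. Cells are
#' numeric; the literal \code{NA} marks a missing value.
#'
#' @param path path to a TSV file.
#' @return a numeric matrix (features x samples) with unique dimnames.
#' @details Ragged rows, duplicated identifiers and non-numeric cells are
#'   rejected with an error naming the offending line or identifier.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("header must contain a feature-id column and at least one sample",
         call. = FALSE)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1L], call. = FALSE)
  body <- fields[-1L]
  n_col <- length(header)
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, widths[bad], n_col), call. = FALSE)
  }
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         feature_ids[duplicated(feature_ids)][1L], call. = FALSE)
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                   dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & cells != "NA")
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at line %d", cells[bad[1L]], i + 1L),
           call. = FALSE)
    values[i, ] <- num
  }
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Values are printed with 17 significant digits so that
#' \code{read_matrix(write_matrix(x)) == x} exactly.
#'
#' @param matrix numeric matrix with unique dimnames.
#' @param path output path.
#' @param id_column name for the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, id_column = "feature") {
  validate_matrix(matrix)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(matrix)), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix)))
    writeLines(paste(c(rownames(matrix)[i], fmt(matrix[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

# Structural checks used by every stage that consumes a matrix.
validate_matrix <- function(matrix, allow_missing = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expected a numeric matrix (features x samples)", call. = FALSE)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix must carry feature rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate feature id: ",
         rownames(matrix)[duplicated(rownames(matrix))][1L], call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample id: ",
         colnames(matrix)[duplicated(colnames(matrix))][1L], call. = FALSE)
  if (!allow_missing && anyNA(matrix))
    stop("matrix contains missing values; impute or filter first",
         call. = FALSE)
  invisible(matrix)
}

#' Read a gene panel (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored. Symbols must be
#' unique; order is preserved.
#'
#' @param path path to a plain-text panel file.
#' @return a character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  lines <- trimws(readLines(path))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  as_gene_panel(genes)
}

# Panel constructor: unique, non-empty symbols.
as_gene_panel <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene panel is empty", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate panel symbol: ",
         genes[duplicated(genes)][1L], call. = FALSE)
  genes
}

#' Read a clinical table with survival annotations
#'
#' @param path TSV with required columns `sample`, `time`, `event`; any
#'   further columns are carried along as covariates.
#' @return a data.frame with validated `time` (> 0) and `event` (0/1).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_clinical(df)
}

as_clinical <- function(df) {
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in clinical table: ",
         df$sample[duplicated(df$sample)][1L], call. = FALSE)
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop_field("time", "survival times must be finite and > 0")
  if (!all(df$event %in% c(0, 1)))
    stop_field("event", "event flag must be 0 (censored) or 1 (death)")
  df
}

#' Read a microvessel-density table
#'
#' @param path TSV with columns `sample` and `vessels_per_hpf`.
#' @return data.frame with non-negative vessel counts per sample.
#' @export
read_mvd <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "vessels_per_hpf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MVD table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$vessels_per_hpf)) || any(df$vessels_per_hpf < 0))
    stop_field("vessels_per_hpf", "vessel counts must be finite and >= 0")
  df
}
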