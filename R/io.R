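# Tabular I/O: expression matrices (first column subject id, gene columns
# with a header row), group labels (two-column TSV) and seed lists.

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of gene identifiers, subjects in rows, with the
#' first column holding subject ids. The delimiter is auto-detected
#' (tab or comma). Missing values are rejected.
#'
#' @param path file path.
#' @return numeric matrix, subjects x genes, with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) validation_error("expression table needs a subject column plus gene columns")
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(X)) validation_error("non-numeric expression values")
  rownames(X) <- as.character(df[[1L]])
  check_expression_matrix(X)
  X
}

#' Write an expression matrix to TSV
#'
#' @param X subjects x genes numeric matrix.
#' @param path output path.
#' @param id_col name of the subject-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, id_col = "subject") {
  check_expression_matrix(X)
  df <- data.frame(rownames(X) %||% paste0("s", seq_len(nrow(X))), X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read group labels from a two-column TSV (subject, group)
#'
#' @param path file path.
#' @param subjects optional subject ids to align the labels to.
#' @return named character vector of group labels.
#' @export
read_groups <- function(path, subjects = NULL) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L) validation_error("group file must have two columns: subject, group")
  groups <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, names(groups))
    if (length(missing))
      validation_error(sprintf("no group label for subject(s): %s",
                               paste(utils::head(missing, 5L), collapse = ", ")))
    groups <- groups[subjects]
  }
  groups
}

#' Read a seed-gene list (one identifier per line, '#' comments allowed)
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  seeds <- lines[!grepl("^(#|$)", lines)]
  if (length(seeds) == 0L) validation_error("empty seed list")
  unique(seeds)
}
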