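#' Write a normalised expression matrix as tab-separated text
#'
#' The matrix is rendered as a header row (`feature_id` followed by the
#' array identifiers) and one row per feature.  Missing cells — features
#' that took part in no pairwise comparison involving that array — are
#' written as the literal `NA`.  Values are printed with `%.17g` so that
#' [read_expression_matrix()] recovers the matrix bit-exactly.
#'
#' @param mat Numeric matrix, features in rows (rownames = feature IDs),
#'   arrays in columns (colnames = array IDs).
#' @param file Destination path or connection.
#' @return Invisibly, `file`.
#' @export
write_expression_matrix <- function(mat, file) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry feature and array names")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("feature and array identifiers must be unique")
  cells <- ifelse(is.na(mat), "NA", sprintf("%.17g", mat))
  dim(cells) <- dim(mat)
  body <- paste(rownames(mat),
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  header <- paste(c("feature_id", colnames(mat)), collapse = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param file Path to the tab-separated matrix file.
#' @return Numeric matrix with feature rownames and array colnames; `NA`
#'   where the file holds the literal `NA`.
#' @export
read_expression_matrix <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE, row.names = 1L,
                           stringsAsFactors = FALSE)
  as.matrix(tab)
}
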