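#' Read / write log2 expression matrices
#'
#' Tab-separated, UTF-8, "." decimal separator; first column gene id, header
#' row of sample ids.
#'
#' @param path File path.
#' @return `read_expression()`: numeric matrix with gene rownames and sample
#'   colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  stopifnot(!anyDuplicated(rownames(m)), !anyDuplicated(colnames(m)),
            all(is.finite(m)))
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix (genes x samples).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation tables
#'
#' Tab-separated with columns `sample_id`, `group`, `batch`, `cohort`.
#' @param path File path.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "batch", "cohort") %in% names(ann)))
  ann
}

#' @rdname read_annotation
#' @param ann Annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene set collections in GMT format
#'
#' One set per line: `set_id TAB description TAB member TAB member ...`.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character member vectors; descriptions
#'   kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1)
  stopifnot(!anyDuplicated(ids))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  stopifnot(all(lengths(sets) > 0))
  structure(stats::setNames(sets, ids),
            descriptions = stats::setNames(
              vapply(fields, `[[`, "", 2), ids))
}

#' @rdname read_gmt
#' @param sets Named list of member vectors.
#' @param descriptions Optional named character of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a ranked gene list (two-column TSV: gene, metric)
#' @param path File path.
#' @return Named numeric vector sorted by decreasing metric.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  stopifnot(!anyDuplicated(names(v)), all(is.finite(v)))
  sort(v, decreasing = TRUE)
}

#' Write a results data.frame as a TSV report
#' @param df Data.frame.
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
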