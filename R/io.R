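# TSV / gene-list / GMT readers and writers. All formats are plain text:
# expression matrices are written with genes as rows and a `gene_id` first
# column, matching the usual bulk RNA-seq exchange layout.

#' Read an expression matrix from TSV
#'
#' Expects a header of sample ids and a first column of gene ids.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  assert_expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  assert_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a TSV with columns sample_id, bioproject, treatment and
#'   optionally tissue, genotype.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_metadata(meta)
}

#' Write a sample metadata table to TSV
#' @param meta data.frame as in [read_metadata()].
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  assert_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor catalog
#'
#' @param path TSV with columns gene_id and family.
#' @return data.frame with columns gene_id, family.
#' @export
read_tf_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "family") %in% names(df))) {
    stop("TF catalog needs columns gene_id and family", call. = FALSE)
  }
  df
}

#' Read / write a one-gene-per-line set file
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @param genes Character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(sort(unique(as.character(genes))), path)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (term -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) character(0) else unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}
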