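#' Read a gene-keyed numeric matrix from TSV
#'
#' Matrices are stored as tab-separated text with a header row and the gene
#' identifier in the first column. Gene identifiers are opaque, case-sensitive
#' strings; any symbol-to-identifier mapping must happen upstream.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_gene_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a gene-keyed numeric matrix to TSV
#'
#' Values are serialized with 15 significant digits so that a fixed seed
#' reproduces byte-identical files.
#'
#' @param m numeric matrix with gene rownames.
#' @param path file path.
#' @param id_col name for the identifier column.
#' @export
write_gene_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(gene = rownames(m),
                   signif(m, 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a tabular block (data frame) as TSV
#' @param path file path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @param df data frame.
#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 15)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report deterministically
#'
#' @param x named list.
#' @param path file path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read one-identifier-per-line gene lists
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @param genes character vector.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-c(1, 2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}
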