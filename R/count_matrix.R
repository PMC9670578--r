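#' Validate a count matrix
#'
#' Checks that `counts` is a non-negative integer-valued matrix with unique
#' row (gene) and column (sample) identifiers, and returns it as a base
#' numeric matrix with dimnames attached.
#'
#' @param counts Matrix-like object of raw counts, genes in rows and samples
#'   in columns.
#' @param gene_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#' @return The validated numeric matrix with rownames/colnames set.
#' @export
as_count_matrix <- function(counts, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("gene_ids/sample_ids lengths must match the matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  if (anyNA(counts)) stop("counts must not contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integer-valued")
  dimnames(counts) <- list(as.character(gene_ids), as.character(sample_ids))
  counts
}

#' Read a count matrix from TSV/CSV or MatrixMarket files
#'
#' TSV/CSV files must have gene identifiers in the first column and sample
#' identifiers in the header. MatrixMarket (`.mtx`) input additionally needs
#' one-column gene and sample identifier files.
#'
#' @param path Path to the counts file.
#' @param genes_path,samples_path Paths to one-column identifier files,
#'   required for `.mtx` input.
#' @return A validated count matrix (see [as_count_matrix()]).
#' @export
read_counts <- function(path, genes_path = NULL, samples_path = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(genes_path) || is.null(samples_path))
      stop("MatrixMarket input requires genes_path and samples_path")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    genes <- genes[nzchar(genes)]
    samples <- samples[nzchar(samples)]
    return(as_count_matrix(m, gene_ids = genes, sample_ids = samples))
  }
  sep <- if (ext == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  as_count_matrix(m, gene_ids = ids, sample_ids = colnames(m))
}

#' Write a numeric gene-by-sample matrix as TSV
#'
#' First column `gene`, one column per sample. Optional comment header lines
#' (prefixed with `#`) record provenance.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param header_lines Optional character vector of comment lines.
#' @export
write_matrix_tsv <- function(m, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a sample metadata table (TSV/CSV)
#' @param path Path; `.csv` is comma-separated, anything else tab-separated.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             comment.char = "#", stringsAsFactors = FALSE)
}
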