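#' Validate and label a gene-by-cell expression matrix
#'
#' Expression data is carried throughout the package as a plain numeric
#' matrix with genes on rows and cells on columns, identified by unique
#' `rownames` (gene ids) and `colnames` (cell ids). This constructor
#' checks the invariants every downstream step relies on: no negative
#' entries, unique non-empty labels, and at least two genes and two cells.
#'
#' @param values numeric matrix (m genes x n cells), non-negative.
#' @param gene_ids character vector of m unique gene identifiers; defaults
#'   to `rownames(values)`.
#' @param cell_ids character vector of n unique cell identifiers; defaults
#'   to `colnames(values)`.
#' @return the validated matrix with dimnames set, classed
#'   `"expression_matrix"` (still usable as an ordinary matrix).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  m <- nrow(values); n <- ncol(values)
  if (m < 2L || n < 2L)
    stop("expression matrix must have at least 2 genes and 2 cells (got ",
         m, " x ", n, ")")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(m))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != m) stop("gene_ids length does not match row count")
  if (length(cell_ids) != n) stop("cell_ids length does not match column count")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative expression at gene '", gene_ids[neg[1, 1]],
         "', cell '", cell_ids[neg[1, 2]], "'")
  dimnames(values) <- list(gene_ids, cell_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x), " genes x ", ncol(x), " cells\n",
      sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV/CSV or MatrixMarket files
#'
#' Dense text input has a header row of cell ids and gene ids in the first
#' column. MatrixMarket (`format = "mtx"`) input requires sidecar label
#' files with one gene id (resp. cell id) per line, in matrix order.
#' Orientation is always genes x cells; pass `transpose = TRUE` if the
#' file stores cells on rows (orientation is never guessed).
#'
#' @param path path to the matrix file.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param gene_file,cell_file label sidecars, required for `"mtx"`.
#' @param transpose logical; transpose after reading.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            gene_file = NULL, cell_file = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "mtx") {
    if (is.null(gene_file) || is.null(cell_file))
      stop("MatrixMarket input requires `gene_file` and `cell_file` sidecars")
    if (!file.exists(gene_file)) stop("gene label file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell label file not found: ", cell_file)
    mat <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (transpose) mat <- t(mat)
    if (length(genes) != nrow(mat))
      stop("gene label file has ", length(genes), " entries but matrix has ",
           nrow(mat), " rows")
    if (length(cells) != ncol(mat))
      stop("cell label file has ", length(cells), " entries but matrix has ",
           ncol(mat), " columns")
    return(expression_matrix(mat, genes, cells))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("expected gene-id column plus at least one cell column")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric expression values in column '", names(df)[-1][bad], "'")
  }
  if (transpose) {
    cells <- genes
    genes <- colnames(mat)
    mat <- t(mat)
    return(expression_matrix(mat, genes, cells))
  }
  expression_matrix(mat, genes, colnames(mat))
}

#' Write an expression matrix
#'
#' @param X matrix with gene/cell dimnames.
#' @param path output path (for `"mtx"`, the matrix file).
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param gene_file,cell_file sidecar label paths for `"mtx"`; default to
#'   `path` with `.genes.txt` / `.cells.txt` appended.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("tsv", "csv", "mtx"),
                             gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(gene_file)) gene_file <- paste0(path, ".genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(path, ".cells.txt")
    Matrix::writeMM(Matrix::Matrix(unclass(X), sparse = TRUE), path)
    writeLines(rownames(X), gene_file)
    writeLines(colnames(X), cell_file)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(X), unclass(X), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(X))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled square matrix (e.g. a cell kernel) as TSV
#'
#' @param M square matrix with identical row/column labels.
#' @param path output path.
#' @export
write_labeled_matrix <- function(M, path) {
  df <- data.frame(id = rownames(M), unclass(M), check.names = FALSE)
  colnames(df) <- c("id", colnames(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
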