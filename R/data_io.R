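#' Construct a gene x sample time-series expression matrix
#'
#' The training substrate for the circadian-time predictor: an expression
#' matrix with one row per unique gene, one column per sample, and an hour
#' label for every sample. Duplicate gene ids are collapsed to their
#' row-wise arithmetic mean on construction.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. No
#'   missing values are allowed.
#' @param gene_ids Character vector of gene identifiers, one per row.
#'   Duplicates are averaged.
#' @param times Numeric vector of sampling times in hours, one per column.
#'   Times need not be equally spaced nor span 24 h.
#' @return An object of class `time_series_matrix` with elements `values`
#'   (unique-gene matrix), `gene_ids` and `times`.
#' @export
time_series_matrix <- function(values, gene_ids, times) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(times) != ncol(values))
    stop("times length (", length(times), ") does not match number of samples (",
         ncol(values), ")")
  if (ncol(values) < 2) stop("at least 2 samples are required")
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite non-negative hours")
  collapsed <- average_duplicate_genes(values, as.character(gene_ids))
  structure(
    list(values = collapsed$values, gene_ids = collapsed$gene_ids,
         times = times),
    class = "time_series_matrix")
}

#' @export
print.time_series_matrix <- function(x, ...) {
  cat(sprintf("time_series_matrix: %d genes x %d samples, span [%g, %g] h\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

#' Average rows sharing a gene identifier
#'
#' Each output row is the arithmetic mean of all input rows carrying the
#' same gene id; output rows keep first-occurrence order. Idempotent.
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids Character vector, one id per row (duplicates allowed).
#' @return A list with `values` (matrix of unique-gene rows) and `gene_ids`.
#' @export
average_duplicate_genes <- function(values, gene_ids) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  if (!anyDuplicated(gene_ids)) {
    rownames(values) <- gene_ids
    return(list(values = values, gene_ids = gene_ids))
  }
  uniq <- unique(gene_ids)
  idx <- split(seq_along(gene_ids), factor(gene_ids, levels = uniq))
  out <- do.call(rbind, lapply(idx, function(i)
    colMeans(values[i, , drop = FALSE])))
  rownames(out) <- uniq
  list(values = out, gene_ids = uniq)
}

#' Read a delimited expression table into a time_series_matrix
#'
#' Expects genes in rows and a header row of sample names (GEO series-matrix
#' orientation); the first column holds gene identifiers. Duplicate gene
#' rows are averaged on read.
#'
#' @param path Path to a TSV/CSV file.
#' @param times Numeric vector of hours (one per sample column), or the path
#'   to a one-column text file of hours.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @param transpose If `TRUE` the file stores samples in rows.
#' @return A [time_series_matrix()].
#' @export
read_expression_table <- function(path, times, sep = "\t", transpose = FALSE) {
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs an id column plus samples")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression cell in ", path)
  if (anyNA(mat)) stop("missing/empty expression cell in ", path)
  if (transpose) {
    mat <- t(mat)
    tmp <- ids
    ids <- colnames(tab)[-1]
    colnames(mat) <- tmp
  }
  if (is.character(times) && length(times) == 1) {
    times <- scan(times, what = numeric(), quiet = TRUE)
  }
  time_series_matrix(mat, ids, times)
}

#' Write a time_series_matrix to a delimited file
#'
#' Inverse of [read_expression_table()]; full double precision.
#'
#' @param x A `time_series_matrix`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_expression_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "time_series_matrix"))
  df <- data.frame(gene = x$gene_ids,
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", if (!is.null(colnames(x$values)))
    colnames(x$values) else paste0("S", seq_along(x$times)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sparse single-cell count container
#'
#' @param counts Non-negative integer matrix or `Matrix::dgCMatrix`,
#'   genes x cells. Duplicate gene ids are allowed and only collapsed at
#'   pseudobulk time (mean after summation).
#' @param gene_ids Character, one per row.
#' @param cell_labels Character, cell-type label per cell.
#' @param sample_labels Character, sample/time-point identifier per cell.
#' @param sample_times Named numeric vector mapping sample label to hour.
#' @param cell_ids Optional per-cell identifiers (barcodes); defaults to
#'   `cell1..cellN`. Bootstrap sampling orders cells by these ids, so
#'   results do not depend on column order.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, gene_ids, cell_labels, sample_labels,
                        sample_times, cell_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  n_cells <- ncol(counts)
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length mismatch")
  if (length(cell_labels) != n_cells) stop("every cell needs a cell_label")
  if (length(sample_labels) != n_cells) stop("every cell needs a sample_label")
  missing_t <- setdiff(unique(sample_labels), names(sample_times))
  if (length(missing_t))
    stop("sample_times missing entries for: ", paste(missing_t, collapse = ", "))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n_cells))
  if (length(cell_ids) != n_cells || anyDuplicated(cell_ids))
    stop("cell_ids must be unique, one per cell")
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_labels = as.character(cell_labels),
         sample_labels = as.character(sample_labels),
         sample_times = sample_times, cell_ids = as.character(cell_ids)),
    class = "cell_matrix")
}

#' Read 10x-style MatrixMarket single-cell counts
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` from a directory
#' (genes as rows) and joins per-cell annotations keyed by barcode.
#'
#' @param dir Directory holding the three files.
#' @param annotations Data frame with columns `barcode`, `cell_type`,
#'   `sample`, or a path to a TSV with those columns.
#' @param sample_times Named numeric vector mapping sample label to hour.
#' @return A [cell_matrix()].
#' @export
read_10x_mtx <- function(dir, annotations, sample_times) {
  mtx_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path))
    if (!file.exists(p)) stop("missing file: ", p)
  counts <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- utils::read.delim(feat_path, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  gene_ids <- feats[[min(2L, ncol(feats))]]
  if (nrow(counts) != length(gene_ids))
    stop("matrix has ", nrow(counts), " rows but features lists ",
         length(gene_ids), " genes")
  if (ncol(counts) != length(barcodes))
    stop("matrix has ", ncol(counts), " columns but barcodes lists ",
         length(barcodes), " cells")
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  unannotated <- setdiff(barcodes, annotations$barcode)
  if (length(unannotated))
    stop("barcodes missing from annotations: ",
         paste(unannotated, collapse = ", "))
  ann <- annotations[match(barcodes, annotations$barcode), ]
  cell_matrix(counts, gene_ids, ann$cell_type, ann$sample, sample_times,
              cell_ids = barcodes)
}
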