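# Reading and writing expression matrices and pipeline side files.
# Matrices are stored genes-in-rows, cells-in-columns: TSV with a gene_id
# first column and cell ids as header, or MatrixMarket triplets with
# genes.tsv / cells.tsv sidecars.

#' Write an expression matrix
#'
#' @param mat Gene-by-cell numeric matrix with dimnames.
#' @param path Output file (TSV) or directory (MTX).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (format == "tsv") {
    dt <- data.table::data.table(gene_id = rownames(mat))
    # %.17g round-trips IEEE doubles exactly
    vals <- data.table::as.data.table(
      matrix(sprintf("%.17g", mat), nrow = nrow(mat),
             dimnames = dimnames(mat)))
    data.table::fwrite(cbind(dt, vals), path, sep = "\t", quote = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sm <- Matrix::Matrix(mat, sparse = TRUE)
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(rownames(mat), file.path(path, "genes.tsv"))
    writeLines(colnames(mat), file.path(path, "cells.tsv"))
  }
  invisible(path)
}

#' Read an expression matrix
#'
#' Validates that gene ids are unique and values non-negative.
#'
#' @param path TSV file or MTX directory written by [write_matrix()].
#' @param format `"tsv"` or `"mtx"`.
#' @return A gene-by-cell numeric matrix with dimnames.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    if (names(dt)[1] != "gene_id") {
      stop("parse error: first column must be 'gene_id' (", path, ")",
           call. = FALSE)
    }
    ids <- dt[[1]]
    mat <- as.matrix(dt[, -1, drop = FALSE])
    rownames(mat) <- ids
  } else {
    sm <- Matrix::readMM(file.path(path, "matrix.mtx"))
    mat <- as.matrix(sm)
    rownames(mat) <- readLines(file.path(path, "genes.tsv"))
    colnames(mat) <- readLines(file.path(path, "cells.tsv"))
  }
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup)) {
    stop("parse error: duplicated gene id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(mat < 0)) {
    stop("parse error: negative expression values", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  mat
}

#' Write per-cell cluster labels
#'
#' @param labels Named vector of cluster labels (names are cell ids).
#' @param path Output TSV path.
#' @param condition Optional per-cell condition tags.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, condition = NULL) {
  dt <- data.table::data.table(cell_id = names(labels),
                               cluster = as.character(labels))
  if (!is.null(condition)) dt$condition <- as.character(condition)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read per-cell cluster labels
#'
#' @param path TSV written by [write_labels()].
#' @return A named character vector (with a `condition` attribute when the
#'   file carries one).
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  out <- stats::setNames(as.character(dt$cluster), dt$cell_id)
  if ("condition" %in% names(dt)) {
    attr(out, "condition") <- stats::setNames(as.character(dt$condition),
                                              dt$cell_id)
  }
  out
}
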