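# PCA projection, suppressed-gene signature detection, and per-cluster gene
# summaries.

#' Project cells onto principal components
#'
#' Column-centred PCA of the cells (observations) over the given gene panel,
#' computed by singular value decomposition of the cell-by-gene matrix. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param rpkm Gene-by-cell expression matrix (rows are the gene panel).
#' @param n_components Number of components to return (default 2).
#' @return An object of class `sc_pca`: `scores` (cells by components),
#'   `variance_explained` (fractions for the returned components),
#'   `variance_explained_all` (all available components, summing to one),
#'   `rotation` and `center`.
#' @export
pca_project <- function(rpkm, n_components = 2L) {
  stopifnot(is.matrix(rpkm))
  n_cells <- ncol(rpkm)
  if (n_components < 1 || n_components > min(n_cells, nrow(rpkm))) {
    stop("'n_components' must lie between 1 and min(n_cells, n_genes)",
         call. = FALSE)
  }
  x <- t(rpkm)
  tot_var <- sum(row_vars(rpkm))
  if (tot_var == 0) {
    stop("constant matrix: no variance to decompose", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2 / sum(pc$sdev^2)
  for (j in seq_len(n_components)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 variance_explained = var_all[seq_len(n_components)],
                 variance_explained_all = var_all,
                 rotation = pc$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 center = pc$center),
            class = "sc_pca")
}

#' @export
print.sc_pca <- function(x, ...) {
  cat("PCA projection: ", nrow(x$scores), " cells, ",
      ncol(x$scores), " components\n", sep = "")
  cat("  variance explained: ",
      paste(format(x$variance_explained, digits = 4), collapse = ", "),
      " (sum ", format(sum(x$variance_explained), digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Suppression rule for cluster-specific silenced genes
#'
#' A gene is flagged for a focal cluster when its mean RPKM exceeds
#' `high_threshold` in every other cluster while, inside the focal cluster,
#' its mean is at most `low_mean` and at least `low_zero_fraction` of its
#' measurements are exactly zero ("completely suppressed").
#'
#' @param high_threshold Minimum cluster-mean RPKM in every non-focal
#'   cluster (default 32).
#' @param low_mean Maximum mean RPKM in the focal cluster (default 1).
#' @param low_zero_fraction Minimum fraction of zeros in the focal cluster
#'   (default 0.9).
#' @return An object of class `sc_suppression_rule`.
#' @export
suppression_rule <- function(high_threshold = 32, low_mean = 1,
                             low_zero_fraction = 0.9) {
  if (!(high_threshold > low_mean) || low_mean < 0) {
    stop("need high_threshold > low_mean >= 0", call. = FALSE)
  }
  if (low_zero_fraction < 0 || low_zero_fraction > 1) {
    stop("'low_zero_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(high_threshold = high_threshold,
                 low_mean = low_mean,
                 low_zero_fraction = low_zero_fraction),
            class = "sc_suppression_rule")
}

#' Detect cluster-specific suppressed-gene signatures
#'
#' Applies the suppression rule to every candidate focal cluster over the
#' union of cluster labels (typically from both conditions analysed
#' jointly) and reports each cluster that ends up with at least one flagged
#' gene.
#'
#' @param rpkm Gene-by-cell expression matrix covering all labelled cells.
#' @param labels Cluster label per cell (character or factor), aligned with
#'   the matrix columns.
#' @param rule An [suppression_rule()].
#' @return A list (possibly empty) of `sc_suppression` objects, each with
#'   `focal_cluster`, `genes` (sorted ids), `per_gene_stats` (gene,
#'   cluster, mean, sd, zero_fraction) and the `rule`.
#' @export
detect_suppressed_genes <- function(rpkm, labels, rule = suppression_rule()) {
  stopifnot(is.matrix(rpkm))
  if (length(labels) != ncol(rpkm)) {
    stop("'labels' must have one entry per cell", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("unknown (missing) label values", call. = FALSE)
  }
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) {
    stop("need at least 2 clusters to apply the suppression rule",
         call. = FALSE)
  }
  means <- vapply(clusters, function(cl)
    rowMeans(rpkm[, labels == cl, drop = FALSE]),
    numeric(nrow(rpkm)))
  zfrac <- vapply(clusters, function(cl)
    rowMeans(rpkm[, labels == cl, drop = FALSE] == 0),
    numeric(nrow(rpkm)))
  ids <- rownames(rpkm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rpkm)))

  out <- list()
  for (ci in seq_along(clusters)) {
    other_min <- do.call(pmin, as.data.frame(means[, -ci, drop = FALSE]))
    flag <- other_min > rule$high_threshold &
      means[, ci] <= rule$low_mean &
      zfrac[, ci] >= rule$low_zero_fraction
    if (any(flag)) {
      genes <- sort(ids[flag])
      stats_df <- cluster_gene_summary(rpkm, labels, genes)
      out[[length(out) + 1L]] <-
        structure(list(focal_cluster = clusters[ci],
                       genes = genes,
                       per_gene_stats = stats_df,
                       rule = rule),
                  class = "sc_suppression")
    }
  }
  out
}

#' @export
print.sc_suppression <- function(x, ...) {
  cat("Suppressed-gene signature: cluster ", x$focal_cluster, ", ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Per-gene, per-cluster expression summary
#'
#' Tidy table of mean, standard deviation and zero fraction of each
#' requested gene in each cluster; a convenient way to inspect marker
#' panels. Genes absent from the matrix are reported via the `missing`
#' attribute (and a message) rather than an error.
#'
#' @param rpkm Gene-by-cell expression matrix.
#' @param labels Cluster label per cell.
#' @param genes Gene ids to summarise (default: all rows).
#' @return A data.frame keyed by (gene, cluster) with columns `mean`, `sd`,
#'   `zero_fraction` and `n_cells`.
#' @export
cluster_gene_summary <- function(rpkm, labels, genes = NULL) {
  stopifnot(is.matrix(rpkm))
  if (length(labels) != ncol(rpkm)) {
    stop("'labels' must have one entry per cell", call. = FALSE)
  }
  labels <- as.character(labels)
  ids <- rownames(rpkm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rpkm)))
  if (is.null(genes)) genes <- ids
  missing_genes <- setdiff(genes, ids)
  if (length(missing_genes)) {
    message("genes absent from the matrix: ",
            paste(missing_genes, collapse = ", "))
  }
  genes <- intersect(genes, ids)
  if (!length(genes)) {
    out <- data.frame(gene = character(0), cluster = character(0),
                      mean = numeric(0), sd = numeric(0),
                      zero_fraction = numeric(0), n_cells = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "missing") <- missing_genes
    return(out)
  }
  clusters <- sort(unique(labels))
  rows <- lapply(clusters, function(cl) {
    sub <- rpkm[genes, labels == cl, drop = FALSE]
    data.frame(gene = genes,
               cluster = cl,
               mean = rowMeans(sub),
               sd = sqrt(row_vars(sub)),
               zero_fraction = rowMeans(sub == 0),
               n_cells = ncol(sub),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing_genes
  out
}

#' Mesenchymal and stemness marker panel
#'
#' Marker ids commonly examined when relating drug-induced subpopulations to
#' epithelial-mesenchymal transition and cancer stem cells; intended for use
#' with [cluster_gene_summary()] on matrices whose rows carry gene symbols.
#'
#' @return A character vector of gene symbols.
#' @export
mesenchymal_markers <- function() {
  c("SOX2", "CD44", "CD24", "CD133", "ALDH", "OCT-4", "FN1", "SNAI2",
    "VIM", "FOXC2", "MMP2", "MMP3", "CDH1", "DSP")
}
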