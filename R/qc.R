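# Stage 1: depth-based cell filtering, prevalence statistics, and
# high-variance gene panel selection.

#' Quality-control configuration
#'
#' @param min_total_count Minimum per-cell total mapped reads; cells below
#'   this are removed (default one million).
#' @param expressed_rpkm_threshold RPKM above which a gene is considered
#'   expressed at an acceptable level (default 32).
#' @param prevalence_cell_fraction Fraction of cells a gene must exceed the
#'   RPKM threshold in, for the "prevalently expressed" summary.
#' @param silent_cell_fraction Fraction of cells a gene must be zero in, for
#'   the "silent" summary.
#' @param variance_top_fraction Fraction of the input gene count kept in the
#'   high-variance panel (default the top fifth percentile).
#' @param require_expressed_in_fraction Fraction of cells a panel gene must
#'   be detected (RPKM > 0) in.
#' @param log_transform If `TRUE`, rank genes by variance of log1p(RPKM)
#'   instead of raw RPKM. Off by default: raw RPKM spreads the
#'   highest-variance genes further apart, which is what drives both the
#'   panel and the low-dimensional projection here.
#' @return An object of class `sc_qc_config`.
#' @export
qc_config <- function(min_total_count = 1e6,
                      expressed_rpkm_threshold = 32,
                      prevalence_cell_fraction = 0.80,
                      silent_cell_fraction = 0.90,
                      variance_top_fraction = 0.05,
                      require_expressed_in_fraction = 0.90,
                      log_transform = FALSE) {
  fr <- c(prevalence_cell_fraction, silent_cell_fraction,
          variance_top_fraction, require_expressed_in_fraction)
  if (any(fr <= 0) || any(fr > 1)) {
    stop("all QC fractions must lie in (0, 1]", call. = FALSE)
  }
  if (min_total_count <= 0 || expressed_rpkm_threshold <= 0) {
    stop("QC thresholds must be positive", call. = FALSE)
  }
  structure(list(min_total_count = min_total_count,
                 expressed_rpkm_threshold = expressed_rpkm_threshold,
                 prevalence_cell_fraction = prevalence_cell_fraction,
                 silent_cell_fraction = silent_cell_fraction,
                 variance_top_fraction = variance_top_fraction,
                 require_expressed_in_fraction = require_expressed_in_fraction,
                 log_transform = log_transform),
            class = "sc_qc_config")
}

#' Remove low-depth cells
#'
#' Drops every cell whose total mapped-read count falls below
#' `cfg$min_total_count`, preserving the order of the remaining cells.
#'
#' @param rpkm Gene-by-cell RPKM matrix.
#' @param totals Per-cell total mapped reads, aligned with the columns of
#'   `rpkm` (names, when present, must match the column names).
#' @param cfg An `sc_qc_config`.
#' @return A list of class `sc_filtered` with elements `matrix` (the
#'   retained columns), `retained_cell_ids`, `removed_cell_ids` and
#'   `totals` (of retained cells).
#' @export
filter_cells <- function(rpkm, totals, cfg = qc_config()) {
  stopifnot(is.matrix(rpkm))
  if (length(totals) != ncol(rpkm)) {
    stop("cell alignment error: 'totals' has ", length(totals),
         " entries for ", ncol(rpkm), " cells", call. = FALSE)
  }
  if (!is.null(names(totals)) && !is.null(colnames(rpkm)) &&
      !identical(names(totals), colnames(rpkm))) {
    stop("cell alignment error: names of 'totals' do not match the matrix ",
         "columns", call. = FALSE)
  }
  keep <- totals >= cfg$min_total_count
  ids <- colnames(rpkm)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(rpkm)))
  structure(list(matrix = rpkm[, keep, drop = FALSE],
                 retained_cell_ids = ids[keep],
                 removed_cell_ids = ids[!keep],
                 totals = totals[keep]),
            class = "sc_filtered")
}

#' @export
print.sc_filtered <- function(x, ...) {
  cat("Cell QC: ", length(x$retained_cell_ids), " cells retained, ",
      length(x$removed_cell_ids), " removed\n", sep = "")
  invisible(x)
}

#' Prevalence statistics of an expression matrix
#'
#' @param rpkm Gene-by-cell RPKM matrix.
#' @param cfg An `sc_qc_config`.
#' @return A list with `prevalent_fraction` (fraction of genes with RPKM
#'   above `expressed_rpkm_threshold` in at least `prevalence_cell_fraction`
#'   of the cells), `silent_fraction` (fraction of genes with zero
#'   expression in at least `silent_cell_fraction` of the cells) and the
#'   corresponding gene counts.
#' @export
prevalence_stats <- function(rpkm, cfg = qc_config()) {
  stopifnot(is.matrix(rpkm), nrow(rpkm) > 0, ncol(rpkm) > 0)
  prev <- rowMeans(rpkm > cfg$expressed_rpkm_threshold) >=
    cfg$prevalence_cell_fraction
  sil <- rowMeans(rpkm == 0) >= cfg$silent_cell_fraction
  list(prevalent_fraction = mean(prev),
       silent_fraction = mean(sil),
       n_prevalent = sum(prev),
       n_silent = sum(sil),
       n_genes = nrow(rpkm))
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}

#' Select the high-variance gene panel
#'
#' Restricts to genes detected (RPKM > 0) in at least
#' `require_expressed_in_fraction` of the cells, ranks the survivors by
#' sample variance of RPKM across cells, and keeps the top
#' `ceiling(variance_top_fraction * n_genes)` where `n_genes` is the
#' *input* gene count (so a 0.05 fraction of 23,398 genes yields a panel of
#' exactly 1,170). Ties in variance are broken lexicographically by gene id.
#' If fewer eligible genes exist than the nominal panel size, all eligible
#' genes are returned with a warning.
#'
#' @param rpkm Gene-by-cell RPKM matrix (typically after [filter_cells()]).
#' @param cfg An `sc_qc_config`.
#' @return A list of class `sc_gene_panel` with `genes` (selected ids in
#'   decreasing variance order), `variances` (named, all ranked genes) and
#'   `n_requested`.
#' @export
select_high_variance_genes <- function(rpkm, cfg = qc_config()) {
  stopifnot(is.matrix(rpkm), nrow(rpkm) >= 1)
  ids <- rownames(rpkm)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(rpkm)))
  x <- if (isTRUE(cfg$log_transform)) log1p(rpkm) else rpkm
  v <- row_vars(x)
  eligible <- rowMeans(rpkm > 0) >= cfg$require_expressed_in_fraction
  if (!any(eligible)) {
    stop("gene panel would be empty: no gene is expressed in at least ",
         format(cfg$require_expressed_in_fraction * 100), "% of cells",
         call. = FALSE)
  }
  n_req <- ceiling(cfg$variance_top_fraction * nrow(rpkm))
  cand <- which(eligible)
  ord <- cand[order(-v[cand], ids[cand])]
  if (length(ord) < n_req) {
    warning("only ", length(ord), " genes satisfy the prevalence ",
            "requirement; panel smaller than the requested ", n_req,
            call. = FALSE)
  }
  sel <- ord[seq_len(min(n_req, length(ord)))]
  structure(list(genes = ids[sel],
                 variances = stats::setNames(v, ids),
                 n_requested = n_req),
            class = "sc_gene_panel")
}

#' @export
print.sc_gene_panel <- function(x, ...) {
  cat("High-variance gene panel: ", length(x$genes), " genes (requested ",
      x$n_requested, ")\n", sep = "")
  invisible(x)
}

#' Run stage-1 quality control
#'
#' Convenience wrapper: [filter_cells()] followed by
#' [select_high_variance_genes()] on the retained cells.
#'
#' @inheritParams filter_cells
#' @return A list with the `filter` result, the `panel`, and
#'   `panel_matrix` (panel genes by retained cells).
#' @export
stage1_qc <- function(rpkm, totals, cfg = qc_config()) {
  fl <- filter_cells(rpkm, totals, cfg)
  panel <- select_high_variance_genes(fl$matrix, cfg)
  list(filter = fl,
       panel = panel,
       panel_matrix = fl$matrix[panel$genes, , drop = FALSE])
}
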