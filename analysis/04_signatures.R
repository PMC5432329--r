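#!/usr/bin/env Rscript
# Combined-population PCA, joint suppressed-gene signature detection over
# the clusters of both conditions, pooled two-sample tests of the
# signature, a per-cell mixture goodness-of-fit check, and the marker-panel
# summary.

source(file.path("analysis", "00_common.R"))

ds <- load_datasets()
qc <- lapply(ds, function(d) stage1_qc(d$rpkm, d$totals))
sel <- list(
  baseline = select_model(t(qc$baseline$panel_matrix), K_range = 1:9,
                          families = "VEI", seed = stage_seed(3)),
  metformin = select_model(t(qc$metformin$panel_matrix), K_range = 1:9,
                           families = "VEI", seed = stage_seed(4)))

# combined PCA of all retained cells
proj <- combined_pca(qc$baseline$filter$matrix, qc$metformin$filter$matrix)
pc2 <- 100 * sum(proj$pca$variance_explained)
sc <- data.table::data.table(cell_id = rownames(proj$pca$scores),
                             proj$pca$scores)
data.table::fwrite(sc, file.path(RESULTS_DIR, "pca_scores.tsv"), sep = "\t")

# joint cluster labels and signature detection on the full gene set
joint <- c(stats::setNames(paste0("B", sel$baseline$labels),
                           names(sel$baseline$labels)),
           stats::setNames(paste0("M", sel$metformin$labels),
                           names(sel$metformin$labels)))
combined <- cbind(qc$baseline$filter$matrix, qc$metformin$filter$matrix)
sigs <- detect_suppressed_genes(combined, joint[colnames(combined)])
stopifnot(length(sigs) == 1)
sig <- sigs[[1]]
writeLines(sig$genes, file.path(RESULTS_DIR, "signature_genes.txt"))
data.table::fwrite(sig$per_gene_stats,
                   file.path(RESULTS_DIR, "signature_cluster_stats.csv"))
planted <- ds$metformin$suppressed_genes[[2]]

# pooled tests: all signature values in the focal cluster against the rest
pooled <- pooled_signature_test(combined, sig$genes, sig$focal_cluster,
                                joint[colnames(combined)])

# goodness-of-fit of a univariate mixture for one cell's panel expression
cell_id <- names(sel$metformin$labels)[1]
cell_vals <- qc$metformin$panel_matrix[, cell_id]
gof_model <- fit_expression_mixture(cell_vals, K_range = 1:4,
                                    seed = stage_seed(5))
gof <- mixture_gof_check(cell_vals, gof_model, n_samples = 10000L,
                         seed = stage_seed(6))

# marker panel (gene symbols are absent from the synthetic universe, so
# this documents the lookup path rather than producing values)
markers <- suppressMessages(
  cluster_gene_summary(combined, joint[colnames(combined)],
                       mesenchymal_markers()))

test_tab <- data.frame(
  quantity = c("signature_size", "matches_planted_set",
               "pooled_mann_whitney_p", "pooled_ks_p",
               "pca_two_component_pct", "gof_cell", "gof_K", "gof_p"),
  value = c(length(sig$genes),
            as.integer(identical(sig$genes, planted)),
            pooled$p_value_u, pooled$p_value_ks, pc2, cell_id,
            gof_model$K, gof$p_value))
data.table::fwrite(test_tab, file.path(RESULTS_DIR, "signature_tests.csv"))

message("signature analysis (results/signature_tests.csv):")
print(test_tab, row.names = FALSE)
message("the focal cluster ", sig$focal_cluster, " (",
        sum(joint[colnames(combined)] == sig$focal_cluster), " cells) ",
        "suppresses exactly the ", length(sig$genes), " planted genes; ",
        "the pooled tests reject at any conventional level; the first two ",
        "principal components explain ", round(pc2, 1), "% of the ",
        "combined variance; ", length(attr(markers, "missing")),
        " marker symbols were ",
        "absent from the synthetic gene universe (reported, not an error)")
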