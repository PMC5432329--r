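# End-to-end orchestration: simulate (or accept) two conditions, QC each,
# cluster each separately, project the combined matrix, detect suppressed
# signatures over the joint cluster labels, and attach the pooled tests.

#' Pipeline configuration
#'
#' @param baseline,metformin `sc_sim_config` objects (or `sc_dataset`
#'   objects generated elsewhere) for the two conditions.
#' @param qc An [qc_config()].
#' @param families,K_range,rule,n_init Clustering settings passed to
#'   [select_model()].
#' @param suppression An [suppression_rule()].
#' @param seed Master seed; fans out to per-stage seeds.
#' @return A list of class `sc_pipeline_config`.
#' @export
pipeline_config <- function(baseline = baseline_preset(),
                            metformin = metformin_preset(),
                            qc = qc_config(),
                            families = "VEI",
                            K_range = 1:9,
                            rule = "max_bic",
                            n_init = 5L,
                            suppression = suppression_rule(),
                            seed = 1L) {
  structure(list(baseline = baseline, metformin = metformin, qc = qc,
                 families = families, K_range = K_range, rule = rule,
                 n_init = n_init, suppression = suppression,
                 seed = as.integer(seed)),
            class = "sc_pipeline_config")
}

cluster_display_labels <- function(labels, prefix) {
  sizes <- sort(table(labels), decreasing = TRUE)
  new_names <- stats::setNames(paste0(prefix, seq_along(sizes)),
                               names(sizes))
  stats::setNames(new_names[as.character(labels)], names(labels))
}

#' Select the high-variance panel of a combined matrix and project it
#'
#' Concatenates the cell-QC'd matrices of both conditions (which share a
#' gene universe), selects the high-variance panel on the combined matrix,
#' and projects all cells onto the leading principal components.
#'
#' @param rpkm_a,rpkm_b Gene-by-cell matrices of retained cells, with
#'   identical row sets.
#' @param cfg An [qc_config()] used for the panel selection.
#' @param n_components Number of principal components.
#' @return A list with the `sc_pca` projection, the combined `panel`, and
#'   the combined panel matrix.
#' @export
combined_pca <- function(rpkm_a, rpkm_b, cfg = qc_config(),
                         n_components = 2L) {
  stopifnot(identical(rownames(rpkm_a), rownames(rpkm_b)))
  combined <- cbind(rpkm_a, rpkm_b)
  panel <- select_high_variance_genes(combined, cfg)
  pm <- combined[panel$genes, , drop = FALSE]
  list(pca = pca_project(pm, n_components = n_components),
       panel = panel,
       panel_matrix = pm)
}

#' Run the full analysis pipeline
#'
#' Stages: generate (or accept) both condition datasets; remove low-depth
#' cells and select each condition's high-variance panel; cluster each
#' condition separately by BIC-selected constrained Gaussian mixtures;
#' project the combined retained cells onto two principal components;
#' detect suppressed-gene signatures over the union of cluster labels; and
#' run the pooled two-sample tests on each detected signature. When
#' `out_dir` is given, every intermediate is written to disk along with a
#' JSON run report.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `sc_run_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sc_pipeline_config"))
  stage_seeds <- with_local_seed(config$seed,
                                 sample.int(.Machine$integer.max, 6))

  as_dataset <- function(x, seed) {
    if (inherits(x, "sc_dataset")) return(x)
    x$seed <- as.integer(seed %% .Machine$integer.max)
    generate_dataset(x)
  }
  ds <- list(baseline = as_dataset(config$baseline, stage_seeds[1]),
             metformin = as_dataset(config$metformin, stage_seeds[2]))

  qc <- lapply(ds, function(d) stage1_qc(d$rpkm, d$totals, config$qc))

  clus <- list(
    baseline = select_model(t(qc$baseline$panel_matrix),
                            K_range = config$K_range,
                            families = config$families, rule = config$rule,
                            n_init = config$n_init, seed = stage_seeds[3]),
    metformin = select_model(t(qc$metformin$panel_matrix),
                             K_range = config$K_range,
                             families = config$families, rule = config$rule,
                             n_init = config$n_init, seed = stage_seeds[4]))

  joint_labels <- c(
    cluster_display_labels(clus$baseline$labels, "B"),
    cluster_display_labels(clus$metformin$labels, "M"))

  fb <- qc$baseline$filter$matrix
  fm <- qc$metformin$filter$matrix
  proj <- combined_pca(fb, fm, config$qc)
  combined <- cbind(fb, fm)

  signatures <- tryCatch(
    detect_suppressed_genes(combined, joint_labels[colnames(combined)],
                            config$suppression),
    error = function(e) list())
  pooled <- lapply(signatures, function(sig)
    pooled_signature_test(combined, sig$genes, sig$focal_cluster,
                          joint_labels[colnames(combined)]))

  cluster_sizes <- lapply(clus, function(cl)
    as.list(table(cluster_display_labels(cl$labels, ""))))
  report <- structure(list(
    seed = config$seed,
    stage_seeds = stage_seeds,
    conditions = names(ds),
    n_cells_input = vapply(ds, function(d) ncol(d$rpkm), numeric(1)),
    n_cells_removed = vapply(qc, function(q)
      length(q$filter$removed_cell_ids), numeric(1)),
    panel_sizes = vapply(qc, function(q) length(q$panel$genes), numeric(1)),
    chosen_K = vapply(clus, function(cl) cl$K, numeric(1)),
    cluster_sizes = lapply(clus, function(cl)
      sort(as.vector(table(cl$labels)), decreasing = TRUE)),
    pca_variance_explained = proj$pca$variance_explained,
    signatures = lapply(signatures, function(sig)
      list(focal_cluster = sig$focal_cluster, n_genes = length(sig$genes))),
    pooled_tests = lapply(pooled, function(p)
      list(u_statistic = p$u_statistic, p_value_u = p$p_value_u,
           ks_statistic = p$ks_statistic, p_value_ks = p$p_value_ks)),
    datasets = ds, qc = qc, clustering = clus, joint_labels = joint_labels,
    projection = proj, signature_objects = signatures,
    pooled_objects = pooled),
    class = "sc_run_report")

  if (!is.null(out_dir)) {
    write_pipeline_outputs(report, out_dir, config)
  }
  report
}

write_pipeline_outputs <- function(report, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character(0)
  add <- function(p) manifest <<- c(manifest, p)
  for (cond in report$conditions) {
    d <- report$datasets[[cond]]
    q <- report$qc[[cond]]
    p <- file.path(out_dir, paste0(cond, "_rpkm.tsv"))
    write_matrix(d$rpkm, p); add(p)
    p <- file.path(out_dir, paste0(cond, "_panel.tsv"))
    writeLines(q$panel$genes, p); add(p)
    p <- file.path(out_dir, paste0(cond, "_labels.tsv"))
    write_labels(cluster_display_labels(report$clustering[[cond]]$labels,
                                        toupper(substr(cond, 1, 1))),
                 p, condition = rep(cond,
                                    length(report$clustering[[cond]]$labels)))
    add(p)
    p <- file.path(out_dir, paste0(cond, "_bic.csv"))
    data.table::fwrite(report$clustering[[cond]]$bic_table, p); add(p)
  }
  p <- file.path(out_dir, "pca_scores.tsv")
  sc <- data.table::data.table(cell_id = rownames(report$projection$pca$scores),
                               report$projection$pca$scores)
  data.table::fwrite(sc, p, sep = "\t"); add(p)
  for (sig in report$signature_objects) {
    p <- file.path(out_dir,
                   paste0("signature_", sig$focal_cluster, ".tsv"))
    writeLines(sig$genes, p); add(p)
  }
  p <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed,
                        families = config$families,
                        K_range = as.integer(config$K_range),
                        rule = config$rule,
                        qc = unclass(config$qc),
                        suppression = unclass(config$suppression)), p)
  add(p)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_payload(report), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add(p)
  report$manifest <- manifest
  invisible(manifest)
}

#' Serializable payload of a run report
#'
#' The deterministic, numeric part of a pipeline run (no large matrices):
#' two runs with the same configuration yield identical payloads.
#'
#' @param report An `sc_run_report`.
#' @return A plain list suitable for JSON serialisation.
#' @export
report_payload <- function(report) {
  list(seed = report$seed,
       n_cells_input = as.list(report$n_cells_input),
       n_cells_removed = as.list(report$n_cells_removed),
       panel_sizes = as.list(report$panel_sizes),
       chosen_K = as.list(report$chosen_K),
       cluster_sizes = report$cluster_sizes,
       pca_variance_explained = report$pca_variance_explained,
       signatures = report$signatures,
       pooled_tests = report$pooled_tests)
}

#' @export
print.sc_run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  for (cond in x$conditions) {
    cat("  ", cond, ": ", x$n_cells_input[[cond]], " cells, ",
        x$n_cells_removed[[cond]], " removed; panel ",
        x$panel_sizes[[cond]], " genes; K = ", x$chosen_K[[cond]],
        " (sizes ", paste(x$cluster_sizes[[cond]], collapse = ", "),
        ")\n", sep = "")
  }
  cat("  PCA variance explained (2 PCs): ",
      format(sum(x$pca_variance_explained), digits = 4), "\n", sep = "")
  if (length(x$signatures)) {
    for (s in x$signatures) {
      cat("  signature: cluster ", s$focal_cluster, ", ", s$n_genes,
          " genes\n", sep = "")
    }
  } else {
    cat("  no qualifying focal cluster\n")
  }
  invisible(x)
}
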