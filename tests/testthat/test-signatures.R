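test_that("PCA variance fractions match the covariance eigenvalues", {
  m <- toy_matrix(10, 30, seed = 41, rfun = rnorm)  # 10 genes x 30 cells
  pc <- pca_project(m, n_components = 5)
  ev <- eigen(cov(t(m)), symmetric = TRUE)$values
  expect_equal(pc$variance_explained_all[1:5], (ev / sum(ev))[1:5],
               tolerance = 1e-10)
  expect_true(all(diff(pc$variance_explained_all) <= 1e-12))
  expect_equal(sum(pc$variance_explained_all), 1)
})

test_that("rank-2 data are fully explained by two components", {
  base <- withr::with_seed(42, matrix(rnorm(2 * 25), 2, 25))
  load <- withr::with_seed(43, matrix(rnorm(8 * 2), 8, 2))
  m <- load %*% base + 5  # 8 genes x 25 cells in a 2-D affine subspace
  pc <- pca_project(m, n_components = 2)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-10)
  expect_error(pca_project(matrix(3, 5, 5)), "constant")
  expect_error(pca_project(m, n_components = 50), "n_components")
})

test_that("PCA sign convention is deterministic", {
  m <- toy_matrix(12, 20, seed = 44, rfun = rnorm)
  p1 <- pca_project(m)
  p2 <- pca_project(m)
  expect_identical(p1$scores, p2$scores)
  for (j in 1:2) {
    load <- p1$rotation[, j]
    expect_gt(load[which.max(abs(load))], 0)
  }
})

test_that("the suppression rule matches a hand-worked toy case", {
  # 5 genes x 9 cells, three clusters of 3 cells
  lab <- rep(c("A", "B", "C"), each = 3)
  m <- rbind(
    g1 = c(50, 60, 55, 40, 45, 50, 0, 0, 0),    # suppressed in C
    g2 = c(50, 60, 55, 40, 45, 50, 5, 0, 0),    # C mean > 1 -> not flagged
    g3 = c(10, 20, 15, 40, 45, 50, 0, 0, 0),    # A mean < 32 -> not flagged
    g4 = c(50, 60, 55, 40, 45, 50, 0, 0, 3),    # C zeros 2/3 < 0.9 and mean 1
    g5 = c(0, 0, 0, 40, 45, 50, 33, 34, 35))    # suppressed in A
  colnames(m) <- paste0("c", 1:9)
  res <- detect_suppressed_genes(m, lab)
  focal <- vapply(res, `[[`, character(1), "focal_cluster")
  expect_setequal(focal, c("A", "C"))
  expect_identical(res[[match("C", focal)]]$genes, "g1")
  expect_identical(res[[match("A", focal)]]$genes, "g5")
  # per-gene stats table carries all clusters for the flagged gene
  st <- res[[match("C", focal)]]$per_gene_stats
  expect_setequal(st$cluster, c("A", "B", "C"))
  expect_equal(st$mean[st$cluster == "C"], 0)
})

test_that("no planting yields an empty result", {
  d <- generate_dataset(test_baseline())
  keep <- !d$is_low_depth
  res <- detect_suppressed_genes(d$rpkm[, keep],
                                 paste0("B", d$true_labels[keep]))
  expect_length(res, 0)
})

test_that("detection equals a nested-loop brute force on random matrices", {
  rule <- suppression_rule(high_threshold = 20, low_mean = 2,
                           low_zero_fraction = 0.5)
  brute <- function(m, lab, rule) {
    cls <- sort(unique(lab))
    out <- list()
    for (focal in cls) {
      genes <- character(0)
      for (g in rownames(m)) {
        ok <- TRUE
        for (other in setdiff(cls, focal)) {
          if (mean(m[g, lab == other]) <= rule$high_threshold) ok <- FALSE
        }
        fm <- m[g, lab == focal]
        if (mean(fm) > rule$low_mean) ok <- FALSE
        if (mean(fm == 0) < rule$low_zero_fraction) ok <- FALSE
        if (ok) genes <- c(genes, g)
      }
      if (length(genes)) out[[focal]] <- sort(genes)
    }
    out
  }
  for (seed in 1:5) {
    m <- withr::with_seed(seed, {
      mm <- matrix(sample(c(0, 0, 1, 30, 60), 40 * 30, TRUE), 40, 30)
      dimnames(mm) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:30))
      mm
    })
    lab <- withr::with_seed(seed + 100, sample(c("A", "B", "C"), 30, TRUE))
    if (length(unique(lab)) < 2) next
    res <- detect_suppressed_genes(m, lab, rule)
    ours <- lapply(res, `[[`, "genes")
    names(ours) <- vapply(res, `[[`, character(1), "focal_cluster")
    bru <- brute(m, lab, rule)
    expect_identical(length(ours), length(bru))
    for (nm in names(bru)) expect_identical(ours[[nm]], bru[[nm]])
  }
})

test_that("label validation rejects missing values and single clusters", {
  m <- toy_matrix(5, 4)
  expect_error(detect_suppressed_genes(m, c("A", "A", NA, "B")), "unknown")
  expect_error(detect_suppressed_genes(m, rep("A", 4)), "at least 2")
  expect_error(detect_suppressed_genes(m, c("A", "B")), "one entry per cell")
})

test_that("cluster summaries reproduce hand-computed statistics", {
  m <- rbind(gX = c(1, 3, 0, 0), gY = c(10, 10, 4, 6))
  colnames(m) <- paste0("c", 1:4)
  lab <- c("P", "P", "Q", "Q")
  st <- cluster_gene_summary(m, lab)
  expect_equal(st$mean[st$gene == "gX" & st$cluster == "P"], 2)
  expect_equal(st$sd[st$gene == "gX" & st$cluster == "P"], sqrt(2))
  expect_equal(st$zero_fraction[st$gene == "gX" & st$cluster == "Q"], 1)
  expect_equal(st$mean[st$gene == "gY" & st$cluster == "Q"], 5)
  # single cluster: per-gene mean equals the row mean
  st1 <- cluster_gene_summary(m, rep("all", 4))
  expect_equal(st1$mean, unname(rowMeans(m)))
  # absent genes (e.g. marker symbols) are reported, not an error
  expect_message(st2 <- cluster_gene_summary(m, lab,
                                             c("gX", mesenchymal_markers())),
                 "absent")
  expect_identical(attr(st2, "missing"), mesenchymal_markers())
  expect_setequal(st2$gene, "gX")
})

test_that("planted suppressed genes are silent in the focal cluster only", {
  d <- generate_dataset(test_metformin())
  keep <- !d$is_low_depth
  lab <- paste0("M", d$true_labels[keep])
  st <- cluster_gene_summary(d$rpkm[, keep], lab, d$suppressed_genes[[2]])
  expect_true(all(st$mean[st$cluster == "M2"] == 0))
  expect_true(all(st$mean[st$cluster != "M2"] > 32))
})
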