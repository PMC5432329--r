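test_that("presets encode the study design and are pure functions", {
  b <- baseline_preset()
  m <- metformin_preset()
  expect_identical(vapply(b$cluster_spec, `[[`, numeric(1), "n_cells"),
                   c(158, 20))
  expect_identical(vapply(m$cluster_spec, `[[`, numeric(1), "n_cells"),
                   c(160, 6, 12))
  expect_equal(b$silent_gene_fraction, 0.80)
  expect_identical(b$n_genes, 23398L)
  expect_identical(b$n_low_depth_cells, 20L)
  expect_identical(m$n_low_depth_cells, 18L)
  expect_identical(m$cluster_spec[[2]]$suppressed_gene_count, 230L)
  expect_identical(baseline_preset(), baseline_preset())
  expect_identical(metformin_preset(), metformin_preset())
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(silent_gene_fraction = 1.4), "configuration error")
  expect_error(sim_config(prevalence_dropout = -0.1), "configuration error")
  expect_error(sim_config(n_low_depth_cells = -1), "configuration error")
  expect_error(sim_config(cluster_spec = list(
    list(n_cells = 10, mean_shift = 0, suppressed_gene_count = 1e6))),
    "expressed genes")
})

test_that("generation is bit-identical under a fixed seed and config", {
  cfg <- test_baseline(seed = 3L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$rpkm, d2$rpkm)
  expect_identical(d1$true_labels, d2$true_labels)
  d3 <- generate_dataset(test_baseline(seed = 4L))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("emitted datasets satisfy the structural invariants", {
  d <- generate_dataset(test_metformin())
  # RPKM/counts consistency, elementwise
  expect_equal(d$rpkm,
               rpkm_from_counts(d$counts, d$gene_lengths_kb, d$totals))
  # planted low-depth cells are exactly the sub-million-total ones
  expect_identical(sum(d$totals < 1e6), 18L)
  expect_identical(unname(d$is_low_depth), unname(d$totals < 1e6))
  # ground-truth labels partition the regular cells into the preset sizes
  sizes <- table(d$true_labels[!d$is_low_depth])
  expect_identical(as.vector(sizes), c(160L, 6L, 12L))
  # suppressed genes are zero in every cell of their component
  sup <- d$suppressed_genes[[2]]
  expect_length(sup, 230)
  focal_cells <- names(d$true_labels)[d$true_labels == 2 & !d$is_low_depth]
  expect_true(all(d$counts[sup, focal_cells] == 0))
  # suppressed genes come from the expressed class: well expressed elsewhere
  other_cells <- names(d$true_labels)[d$true_labels != 2 & !d$is_low_depth]
  expect_true(all(rowMeans(d$rpkm[sup, other_cells]) > 32))
})

test_that("both conditions share the same gene universe", {
  db <- generate_dataset(test_baseline())
  dm <- generate_dataset(test_metformin())
  expect_identical(rownames(db$rpkm), rownames(dm$rpkm))
  expect_identical(db$gene_lengths_kb, dm$gene_lengths_kb)
  expect_identical(db$program_genes, dm$program_genes)
})

test_that("rpkm_from_counts implements the RPKM formula", {
  # round numbers: 10 reads, 2 kb, one million total -> 5 RPKM
  counts <- matrix(c(10, 999990), ncol = 1,
                   dimnames = list(c("gA", "gB"), "cell1"))
  r <- rpkm_from_counts(counts, c(2, 1), totals = 1e6)
  expect_equal(r["gA", "cell1"], 5.0)
  # an all-zero gene stays all zero
  counts0 <- toy_matrix(4, 3, rfun = function(n) rpois(n, 5))
  counts0[2, ] <- 0
  expect_true(all(rpkm_from_counts(counts0, rep(1, 4))[2, ] == 0))
  # random matrix matches the brute-force loop oracle
  cm <- toy_matrix(20, 5, seed = 7, rfun = function(n) rpois(n, 30))
  len <- withr::with_seed(8, runif(20, 0.5, 5))
  tot <- colSums(cm)
  expect_equal(rpkm_from_counts(cm, len), rpkm_loop_oracle(cm, len, tot))
  # zero-total cells are named in the error
  cm[, 2] <- 0
  expect_error(rpkm_from_counts(cm, len), "c002")
})
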