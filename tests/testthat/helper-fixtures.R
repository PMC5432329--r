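# Shared fixtures. The reduced presets keep the full component structure
# (158/20 and 160/6/12 cells, 230 planted suppressed genes) on a 5,000-gene
# universe so whole-pipeline tests run in seconds. With far fewer genes the
# 230 planted suppressions would strip most of a cell's transcriptome and
# push the suppressed cells under the one-million-read depth cut.

test_n_genes <- 5000L

test_baseline <- function(seed = 11L) baseline_preset(seed, test_n_genes)
test_metformin <- function(seed = 12L) metformin_preset(seed, test_n_genes)

# small deterministic matrix with gene/cell names
toy_matrix <- function(n_genes, n_cells, seed = 1, rfun = stats::runif) {
  withr::with_seed(seed, {
    m <- matrix(rfun(n_genes * n_cells), nrow = n_genes)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("c%03d", seq_len(n_cells)))
    m
  })
}

# brute-force elementwise RPKM, loop form
rpkm_loop_oracle <- function(counts, len_kb, totals) {
  out <- counts * NA_real_
  for (g in seq_len(nrow(counts))) {
    for (ce in seq_len(ncol(counts))) {
      out[g, ce] <- counts[g, ce] / (len_kb[g] * totals[ce] / 1e6)
    }
  }
  out
}
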