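# scmixture

Model-based clustering and rare-subpopulation detection for single-cell
RNA-seq expression matrices.

Deeply sequenced scRNA-seq experiments on nominally homogeneous cell lines
often hide small subpopulations whose drug response differs radically from
the bulk — for example a handful of cells that switch off an entire gene
program. `scmixture` implements a two-stage pipeline for finding them, for
computational biologists analysing gene-by-cell RPKM matrices (~23,000
genes, a few hundred cells per condition):

1. **Stage 1 — QC and gene panel.** Cells with fewer than one million
   mapped reads are removed; the clustering panel is the top fifth
   percentile of genes by raw-RPKM variance among genes detected in at
   least 90% of cells (1,170 genes from a 23,398-gene annotation).
2. **Stage 2 — constrained Gaussian mixtures.** Cells are modelled as
   draws from a finite Gaussian mixture with covariances
   `Sigma_k = lambda_k * A_k` (diagonal shape `A_k`, `det A_k = 1`;
   families EII/VII/EEI/VEI/EVI/VVI, default VEI = varying volume, equal
   shape), fitted by EM with Ward + k-means++ initialisation and selected
   by BIC (`2 loglik - n_params log n`) over K = 1..9. Partitions are
   corroborated by Ward hierarchical clustering (adjusted Rand index).

On top of the clustering the package detects **suppressed-gene
signatures** — genes with mean RPKM > 32 in every cluster except one focal
cluster where they are completely suppressed (mean ≤ 1 and ≥ 90% zeros) —
and attaches pooled Mann-Whitney U and Kolmogorov-Smirnov tests, a
sampling-based mixture goodness-of-fit check, and per-cluster gene
summaries. A seeded synthetic generator (Poisson counts over log-normal
rates, 80% silent genes, planted cluster structure and suppression)
makes every stage testable end to end; see the methods vignette
(`vignettes/model-based-clustering.Rmd`) for the model and all design
choices.

## Worked example

Run the whole pipeline on a reduced 5,000-gene version of the two built-in
presets (a 158 + 20-cell untreated condition and a 160 + 6 + 12-cell
treated condition with 230 genes suppressed in the 6-cell component):

```r
library(scmixture)
cfg <- pipeline_config(baseline = baseline_preset(n_genes = 5000),
                       metformin = metformin_preset(n_genes = 5000),
                       seed = 7)
report <- run_pipeline(cfg)
print(report)
#> Pipeline run (seed 7)
#>   baseline: 198 cells, 20 removed; panel 250 genes; K = 2 (sizes 158, 20)
#>   metformin: 196 cells, 18 removed; panel 250 genes; K = 3 (sizes 160, 12, 6)
#>   PCA variance explained (2 PCs): 0.9861
#>   signature: cluster M3, 230 genes
```

Reading the output: stage 1 removed exactly the planted low-depth cells;
BIC chose two baseline clusters and three treated clusters whose sizes
match the planted design; the first two principal components of the
combined data carry 98.6% of the variance; and the joint suppression rule
recovered a 230-gene signature in the 6-cell cluster (here labelled M3 —
cluster ids are ordered by size and carry no meaning). The pooled test
results and per-stage objects are in `report$pooled_tests`,
`report$clustering`, etc.; with an `out_dir` argument every intermediate
is written to disk alongside a JSON run report.

The numbered scripts under `analysis/` run the same stages at full scale
(23,398 genes) and write their tables under `results/`:
`01_simulate.R`, `02_qc.R`, `03_cluster.R`, `04_signatures.R`.

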