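# Shared settings for the analysis scripts. Every script can be run on its
# own: intermediate matrices live under scratch/sim/ (large, regenerated on
# demand), result tables under results/.

library(scmixture)

ANALYSIS_SEED <- 20170310L
SIM_DIR <- file.path("scratch", "sim")
RESULTS_DIR <- "results"
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# deterministic per-stage seeds fanned out from the master seed
stage_seed <- function(i) {
  with_local_seed(ANALYSIS_SEED, sample.int(.Machine$integer.max - 1L, 8))[i]
}

# generate (or load) both condition datasets
load_datasets <- function() {
  list(baseline = generate_dataset(baseline_preset(seed = stage_seed(1))),
       metformin = generate_dataset(metformin_preset(seed = stage_seed(2))))
}
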