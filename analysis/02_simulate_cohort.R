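#!/usr/bin/env Rscript

# Ground-truthed synthetic cohort.
#
# Simulates the default benchmark cohort: 9 embryos x 200 barcoded
# precursors on the 7-element cassette, fate classes MM/HG/HM/MA/uni at
# the configured probabilities, log-normal clone sizes, PCR noise,
# amplification bias, 5% chimeras and sub-threshold error barcodes.

suppressMessages(library(loxtrace))
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seed <- 1L
cfg <- cohort_config()
cohort <- simulate_cohort(cfg, seed = seed)
print(cohort)
cat(sprintf(
  "Truth: %d clones over %d barcodes; %d chimera and %d error artifact records.\n",
  nrow(cohort$truth), length(unique(cohort$truth$key)),
  sum(cohort$artifacts$type == "chimera"), sum(cohort$artifacts$type == "error")
))

meta <- c(seed = as.character(seed))
write_tsv_meta(cohort$truth, file.path(out_dir, "cohort_truth.tsv"), meta = meta)
write_tsv_meta(cohort$truth_cells, file.path(out_dir, "cohort_truth_cells.tsv"), meta = meta)
write_tsv_meta(cohort$counts, file.path(out_dir, "cohort_counts.tsv"), meta = meta)
write_tsv_meta(cohort$samples, file.path(out_dir, "cohort_samples.tsv"), meta = meta)
write_tsv_meta(cohort$artifacts, file.path(out_dir, "cohort_artifacts.tsv"), meta = meta)
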