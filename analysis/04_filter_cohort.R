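#!/usr/bin/env Rscript

# Filtering cascade: raw counts -> informative barcodes.
#
# Applies, in order: structure filter (malformed, 1-element, unrecombined
# reference), PCR-chimera parent filter (< 10% of combined superset
# parents), 100-read detection threshold, reads-per-cell normalisation,
# and the clonality filter (class diversity > 2000, single embryo).
# Reads the cohort written by 02_simulate_cohort.R.

suppressMessages(library(loxtrace))
out_dir <- "results/analysis"
counts <- read_tsv_meta(file.path(out_dir, "cohort_counts.tsv"))
samples <- read_tsv_meta(file.path(out_dir, "cohort_samples.tsv"))
artifacts <- read_tsv_meta(file.path(out_dir, "cohort_artifacts.tsv"))
table7 <- read_barcode_table(file.path(out_dir, "barcode_table_7el.tsv"))
spec7 <- cassette_spec(n_elements = 7)

res <- filter_barcodes(counts, samples, table7, filter_config(), spec7)
cat(sprintf(
  "%d raw count entries -> %d informative (barcode, sample) entries over %d barcodes.\n",
  nrow(counts), nrow(res$informative), length(unique(res$informative$key))
))
print(table(res$audit$stage))
chim <- artifacts[artifacts$type == "chimera", ]
cat(sprintf(
  "Chimeras in the informative set: %d of %d generated.\n",
  sum(unique(chim$key) %in% res$informative$key), nrow(chim)
))
write_tsv_meta(res$informative, file.path(out_dir, "informative_barcodes.tsv"))
write_tsv_meta(res$audit, file.path(out_dir, "filter_audit.tsv"))
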