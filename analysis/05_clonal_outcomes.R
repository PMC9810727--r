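#!/usr/bin/env Rscript

# Clonal outcomes and lineage biomass.
#
# Labels every informative barcode by its lineage presence pattern
# (HG haemangioblast, HM haematomesoblast, MA mesenchymoangioblast,
# MM multi-outcome mesoderm, uni-<group>), summarises embryo
# reproducibility, computes per-lineage biomass from quantifiable
# (5-9-element) barcodes, and reports population-sharing and
# quantifiable-fraction statistics.

suppressMessages(library(loxtrace))
out_dir <- "results/analysis"
informative <- read_tsv_meta(file.path(out_dir, "informative_barcodes.tsv"))
counts <- read_tsv_meta(file.path(out_dir, "cohort_counts.tsv"))

records <- presence_and_label(informative)
cat("Outcome labels across informative barcodes:\n")
print(table(records$label))

rep_tab <- embryo_reproducibility(records)
write_tsv_meta(rep_tab, file.path(out_dir, "embryo_reproducibility.tsv"))

quant <- quantifiable_subset(records)
bio <- biomass(quant)
cat("\nBiomass (% of each lineage group by ancestral outcome):\n")
print(as.data.frame(dplyr::arrange(bio, group, dplyr::desc(pct))), digits = 3)
write_tsv_meta(records, file.path(out_dir, "outcome_records.tsv"))
write_tsv_meta(bio, file.path(out_dir, "biomass.tsv"))

sf <- shared_fraction(informative, "Mac", "HPC")
cat(sprintf("\nShared clonal ancestry Mac vs HPC: %.1f%% / %.1f%% of each side's biomass.\n",
            sf[1], sf[2]))

qf <- do.call(rbind, lapply(split(counts, sub("_.*", "", counts$sample_id)),
                            quantifiable_fraction))
cat("\nQuantifiable (complex 5-9-element) fraction per embryo, raw counts:\n")
print(round(qf, 1))
write_tsv_meta(tibble::tibble(embryo_id = rownames(qf),
                              pct_reads = qf[, 1], pct_barcodes = qf[, 2]),
               file.path(out_dir, "quantifiable_fraction.tsv"))
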