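Package: loxtrace
Title: Clonal Lineage Tracing with Cre-lox Recombination Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-diversity Cre-lox cassette barcoding
    of mouse embryos. Enumerates the recombination state space of a loxP
    cassette (inversions and excisions under a minimal inter-site distance
    rule) to assign each barcode a complexity (minimal number of
    recombination steps) and a size/complexity class diversity; extracts
    barcodes from paired-end amplicon reads with middle-element imputation;
    applies the filtering cascade (structure, PCR-chimera parent filter,
    read threshold, reads-per-cell normalisation, class-diversity and
    embryo-uniqueness clonality filters) that defines informative barcodes;
    classifies clonal outcomes (haemangioblast, haematomesoblast,
    mesenchymoangioblast, multi-outcome mesoderm) and quantifies lineage
    biomass; and generates ground-truthed synthetic cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
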