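# loxtrace

In vivo clonal lineage tracing with Cre-lox recombination barcodes.

A barcoding cassette — 13 short unique DNA elements interleaved with 14
alternately oriented loxP sites — is shuffled by transient Cre exposure
into a heritable barcode: head-to-head loxP pairs invert the intervening
segment, head-to-tail pairs excise it, subject to an 82 bp minimal
distance between recombining sites. Reading the barcodes out of sorted
cell populations by amplicon sequencing identifies clones shared between
lineages. The analytical difficulty is that *frequent* barcodes arise
independently in many cells: clonal conclusions require knowing, for
every barcode, the minimal number of recombination events able to
produce it (its **complexity**) and how many distinct barcodes its
(size, complexity) class can hold (its **diversity**).

`loxtrace` implements the full analysis for developmental biologists
using such cassettes:

* **state-space engine** — enumerate all reachable barcodes
  breadth-first (C++ core), so that complexity = BFS generation;
  compute class diversities; targeted complexity queries for observed
  barcodes. Under the distance rule no event moves fewer than 3
  elements, so reachable sizes are 13, 9, 7, 5, 3, 1 (never 11);
* **extraction** — dual-index demultiplexing and slot-anchored element
  calling from paired FASTQ, with minimal-complexity imputation of the
  one middle element that 300 bp paired reads cannot cover on
  full-length barcodes;
* **filtering cascade** — structure filter, PCR-chimera parent filter
  (< 10% of combined superset parents), 100-read detection threshold,
  reads-per-cell normalisation, and the clonality filter (class
  diversity > 2000, single embryo) defining **informative barcodes**;
* **clonal outcomes** — haemangioblast (HG: blood + endothelium),
  haematomesoblast (HM: blood + mesenchyme), mesenchymoangioblast (MA),
  multi-outcome mesoderm (MM), and uni-lineage labels; embryo
  reproducibility; per-lineage **biomass** from quantifiable
  (5–9-element) barcodes; population sharing, quantifiable fractions
  and replicate concordance;
* **synthetic cohorts** — a ground-truthed generator (clone fates,
  log-normal clone sizes, PCR noise, size-class amplification bias,
  chimeras, error barcodes) so every stage is testable without any
  sequencing download, plus `evaluate_recovery()` to score the pipeline
  against truth.

The methods vignette (`vignettes/loxcode-clonal-tracking.Rmd`) explains
the models, conventions and their rationale.

## Worked example

```r
library(loxtrace)

spec <- cassette_spec(n_elements = 13)
valid_events(make_reference(spec), spec) |> nrow()
#> [1] 66                      # 36 inversions + 30 excisions on the intact cassette

tb <- enumerate_reachable(spec, max_depth = 3)
tb
#> <barcode_table> 13-element cassette: 28,194 barcodes, max complexity 3 (depth-bounded: diversities approximate)
sort(unique(tb$size))
#> [1]  1  3  5  7  9 13       # 11-element barcodes can never form

# ground-truthed synthetic cohort: 9 embryos x 200 clones, 5% chimeras
cohort <- simulate_cohort(cohort_config(), seed = 1)
res <- evaluate_recovery(cohort)
c(res$precision, res$recall, res$label_accuracy)
#> [1] 1.0000000 1.0000000 0.9977778
res$chimeras_surviving_parent_filter
#> [1] 0                       # every simulated chimera is caught by the parent filter
```

The numbers mean: on the default noisy benchmark every informative
barcode corresponds to a true clone and vice versa, 99.8% of clones get
their true fate label, and the 10%-of-parents rule removes all 244
simulated PCR chimeras.

The `analysis/` directory holds the numbered workflow
(`01_enumerate_cassette.R` … `06_recovery_benchmark.R`): cassette
enumeration, cohort simulation, FASTQ round trip, filtering, outcome and
biomass analysis, and the recovery benchmark. Each script prints what it
found and writes its tables under `results/analysis/`.

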