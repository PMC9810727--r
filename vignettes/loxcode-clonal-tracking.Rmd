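---
title: "Clonal tracking with Cre-lox recombination barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal tracking with Cre-lox recombination barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtrace)
```

# The cassette model

The barcoding construct is an array of 13 short (8–14 bp) unique DNA
elements separated by 14 loxP sites in strictly alternating orientation,
inserted in a safe-harbour locus. Transient Cre exposure recombines pairs
of loxP sites: head-to-head pairs invert the intervening segment
(elements reversed and orientation-flipped), head-to-tail pairs excise
it. The resulting element arrangement is a heritable DNA barcode read
out by amplicon sequencing of sorted cell populations: two cells (or
populations) carrying the same rare barcode share a clonal ancestor.

`loxtrace` represents a cassette state as a signed element vector
(`+i` = element *i* in reference orientation, `-i` = inverted),
serialised as keys like `"+1-4-3-2+5"`. Two structural facts make this
compact representation sufficient:

* site orientations always alternate, and every legal event preserves
  the alternation (inversions join opposite-oriented sites and flip the
  interior; excisions join same-oriented sites and merge them);
* the leftmost site survives every event, so the whole site-orientation
  vector of any reachable state is implied by the element count.

Both facts are *checked*, not assumed: the test suite compares the
engine against an independently written naive oracle that carries
explicit site-orientation vectors and applies the rewriting rules
literally.

## The distance rule and the size spectrum

Cre recombination is inefficient between loxP sites closer than 82 bp.
We measure the distance between two sites as the gap strictly between
them: intervening element lengths plus 34 bp per intervening loxP site.
With element lengths anywhere in 8–14 bp, a gap spanning one element is
at most 14 bp and one spanning two is at most 62 bp — both always
illegal — while any three-element gap is at least 8+34+8+34+8 = 92 bp,
always legal. Hence:

* inversions move an odd number (≥ 3) of elements; excisions remove an
  even number ≥ 4;
* reachable barcode sizes from the intact 13-element cassette are
  13, 9, 7, 5, 3 and 1 — an 11-element barcode can never form;
* element counts of reachable states are always odd.

Since the legality pattern is the same for every length assignment in
the design range, the default spec uses 10 bp for every element; the
distance rule is nonetheless re-evaluated on each intermediate state,
not on the reference geometry.

```{r events}
spec13 <- cassette_spec(n_elements = 13)
ev <- valid_events(make_reference(spec13), spec13)
table(ev$kind)
```

# Complexity and the clonality problem

The same low-complexity barcode (e.g. the whole-cassette inversion, one
recombination step) arises independently in many cells and many embryos,
so its presence in two populations says nothing about shared ancestry.
`enumerate_reachable()` builds the barcode table breadth-first from the
intact cassette, generation-synchronously, so the generation at which a
barcode first appears is its **complexity** — the minimal number of
recombination events able to produce it. The breadth-first closure is
implemented in C++; the 13-element cassette's full closure (>3×10^10
barcodes) is far beyond a desktop, so unbounded builds of large
cassettes require an explicit opt-in, while depth-bounded builds (the
complexity ≤ 3 table has ~28k entries) run in well under a second.
On-demand `complexity_of()` queries run a targeted search that only
expands states retaining every element id of the query (an excision that
loses a needed element can never lead to it) up to a depth cap, and
report "not found within cap" rather than guessing.

Barcode classes defined by (size, complexity) have widely varying
combinatorial diversity, and only barcodes from diverse classes
(> 2000 possible combinations) are plausibly unique to one clone.

# From reads to counts

Libraries are dual-indexed amplicons spanning the cassette between two
constant flanking arms, with a short random stagger for cluster
diversity. Extraction is deliberately slot-anchored rather than
alignment-based: elements sit at stereotyped positions separated by
34 bp loxP spacers, so each slot is compared against all element
sequences in both orientations and called as the unique nearest within
one mismatch. Element sequences differ pairwise by at least two
nucleotides in either orientation (enforced at spec construction, and by
the generator of synthetic element sets), which makes one-mismatch calls
unambiguous; indels are treated as rejections.

Mates are scanned inward from their flanks and merged. When neither mate
reaches the opposite flank, every odd candidate element count is tried
and the read is kept only if exactly one count merges consistently. With
300 bp paired reads only full-length (13-element) amplicons leave a
slot uncovered — exactly one, in the middle. Its identity is the single
absent element id; its orientation is chosen by completing the barcode
both ways and taking the completion with the smaller complexity (the
minimal-steps assumption); ties are flagged ambiguous and excluded. The
round-trip property (simulate reads → extract → identical counts) is
asserted in the tests, with and without substitution errors.

# The filtering cascade

Raw per-sample counts pass five stages, in a fixed order; every removal
is recorded with its stage in an audit table.

1. **Structure**: unparseable keys, 1-element barcodes and the
   unrecombined reference are removed (limited-diversity classes);
   *recombined* full-length barcodes are retained.
2. **PCR parent filter**: within a library, any barcode whose
   signed-element set is strictly contained in another's is a potential
   template-switch chimera of it; it is removed when its reads are
   strictly below 10% of all such parents' combined reads. Containment
   is orientation-sensitive — chimeras preserve segment orientations.
3. **Detection threshold**: entries under 100 reads are removed
   (sequencing errors, contamination); 100 reads exactly is kept.
4. **Normalisation**: reads become cell-equivalents,
   `reads × cells_sorted / total_reads`, per sample, making clone sizes
   comparable across libraries of different depth.
5. **Clonality**: keep barcodes whose (size, complexity) class diversity
   strictly exceeds 2000 *and* which occur in exactly one embryo of
   their dataset (an experiment-level grouping, configurable).

Boundary conventions are literal: ≥ 100 reads kept, < 10% removed,
> 2000 kept. The cascade is monotone (tightening any threshold never
adds a barcode), which is asserted as a property test.

Survivors are **informative barcodes**: each is treated as marking one
clone in one embryo.

# Outcomes and biomass

Populations map to lineage groups (default: EryP; Haem = HPC +
megakaryocyte + macrophage; Endo; Mes). A clone's presence vector over
groups (any positive cell-equivalents, by default) determines its
outcome label on three meta-lineages — blood (EryP and/or Haem),
endothelium, mesenchyme:

| present | label |
|---|---|
| blood + Endo, no Mes | HG (haemangioblast) |
| blood + Mes, no Endo | HM (haematomesoblast) |
| Endo + Mes, no blood | MA (mesenchymoangioblast) |
| blood + Endo + Mes | MM (multi-outcome mesoderm) |
| one group only | uni-\<group\> |
| EryP + Haem only | EryP+Haem |

A blood-presence pattern such as {EryP, Haem, Endo} is HG, not MM:
multi-outcome mesoderm requires all three meta-lineages. Because
presence thresholds at zero, labels are invariant to rescaling and to
population order; a configurable minimal fraction-of-clone-biomass per
group is provided because no presence threshold beyond detectability is
inherent to the data.

**Biomass** answers the converse question: what fraction of each
lineage's cells descends from ancestors of each fate? Per group, the
cell-equivalents of quantifiable barcodes are summed by label and
normalised to 100%. Only 5–9-element barcodes are quantifiable: 1–3- and
13-element size classes amplify non-linearly (bead clean-up, PCR and
sequencing biases), so they are kept for presence analysis but excluded
from biomass. Companion statistics: `shared_fraction()` (the share of
each of two populations' biomass carried by barcodes present in both),
`quantifiable_fraction()` (read- and barcode-weighted share of complex
5–9-element barcodes, the induction time-course statistic) and
`replicate_concordance()` (shared barcodes across technical replicates,
Jaccard and per-replicate conventions).

# The synthetic cohort generator

No sequencing data accompanies the study, so the generator is the
package's test bed: it emulates the statistical structure the analysis
assumes and exposes every nuisance parameter.

* **Cassette**: 7 elements by default. Its full closure (18,728
  barcodes) is exact in ~0.05 s, so class diversities carry no
  approximation, while the 82 bp legality pattern (no 1–2-element
  events) matches the real cassette. Its diverse classes (> 2000
  combinations) are the full-size complexity 5–7 classes; sizes 3 and 1
  mirror the real cassette's limited-diversity short classes. A
  9-element cassette (1.5M barcodes, ~1 min) and the capped-depth
  13-element mode remain available.
* **Barcodes**: each precursor draws Poisson(λ = 5) recombination
  events and walks the state space via `sample_recombination_path()`;
  λ = 5 stands for accumulated Cre exposure over a ~24 h induction
  window. Random walks concentrate on low-complexity barcodes — the
  very reason the clonality filter exists — so with
  `ensure_informative` (the default for recovery benchmarking) draws
  are rejected until the clone is informative by construction (diverse
  class, cohort-unique, never signed-subset-nested within an embryo),
  falling back after a few attempts to a uniform draw from the
  diverse-class pool. With `ensure_informative = FALSE` the raw walk
  statistics are kept, reproducing the recurrence of low-complexity
  barcodes across embryos.
* **Clone sizes**: log-normal cells per contributed population
  (meanlog = log 300, sdlog = 1) — heavy-tailed clone output is the
  stressor for biomass quantification; three to four days of expansion
  make a few hundred cells per lineage a realistic median. A floor of
  20 cells encodes the method's detection sensitivity: 20 cells ×
  10 reads/cell × 0.5 (strongest under-amplification) = 100 reads, the
  detection threshold, so modelled clones are detectable by design and
  sub-sensitivity contributions are out of scope.
* **Reads**: `cells × 10 × size_bias × LogNormal(sd = 0.3)`, the bias
  defaulting to 2× for 1-element and 0.5× for full-length barcodes
  (over- and under-representation of the extreme size classes).
* **Artifacts**: chimeras are single-excision products of a sampled
  parent carrying 1–9% of the parent's reads (template-switch
  deletions; always signed-subsets, asserted) — raise the fraction
  above 10% to study filter failure; error barcodes carry 10–99 reads,
  below the detection threshold. Rates: 0.05 and 0.02 per clone per
  library.
* **Samples**: one library per (embryo, population); `cells_sorted` is
  the sample's total barcoded cells, so in the noise-free limit
  cell-equivalents equal true cells exactly.

`evaluate_recovery()` scores a pipeline run against truth: noise-free
cohorts must give precision = recall = label accuracy = 1 and zero
biomass error; under the default noisy conditions fate-class frequency
estimates stay within Monte-Carlo range of the configured
probabilities, per-lineage biomass errors stay within a few percentage
points, and every generated chimera is removed by the parent filter
alone.

What passing these tests does *not* show: the generator draws
substitution errors uniformly, models chimeras as single excisions only,
and knows nothing of bead chemistry, index hopping, or embryo-to-embryo
asynchrony. Results on real libraries depend on those unmodelled
features, most visibly through the 5–9-element linearity assumption.

# Numerical and design choices

* Distance is the gap *between* recombining sites, excluding their own
  34 bp; this is the only convention that reproduces the observed size
  spectrum (no 11-element barcodes; 9 the largest recombined size below
  13).
* Events are ordered by (site_a, site_b); ordering never affects
  results but fixes logs and seeded draws.
* Breadth-first expansion is generation-synchronous so complexity equals
  BFS depth regardless of within-generation order.
* Equal-complexity imputation candidates are ambiguous, not guessed;
  beyond-cap complexity queries return "unknown", and the clonality
  filter excludes (and logs) barcodes with unknown complexity.
* `parent` in the chimera filter means strict signed-set superset in the
  same library. Treating orientation as irrelevant, or requiring
  subsequence order, are plausible alternatives; the choice is a
  parameterisable predicate and the orientation-sensitive strict-set
  reading is the default because template switching preserves segment
  orientations.
* `total_reads` for normalisation is the sample's total raw reads
  before filtering (computed from the incoming counts unless supplied),
  and uniqueness is assessed within a configurable embryo grouping.
* Problem sizes in tests and scripts: 7-element cassette, 9 × 200
  cohorts, 20-seed benchmarks, ~500-read FASTQ fixtures — chosen so the
  whole validation runs in minutes on one core while every code path
  (including full-length imputation) is exercised.

# Known limitations

* Complexities for observed 13-element-cassette barcodes are exact only
  up to the search cap; rare ultra-complex barcodes are excluded rather
  than mislabelled.
* The extractor requires equal element lengths (slot anchoring); the
  8–14 bp design range is supported by the model but read simulation
  uses a single length.
* Heatmap rendering is out of scope; the package exports matrices and
  tables only.
* The published biological percentages (e.g. macrophage–microglia
  sharing, replicate concordance ranges) cannot be recomputed without
  the unreleased sequencing data; the corresponding statistics are
  instead validated on synthetic cohorts with known truth.
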