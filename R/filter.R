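#' Filtering-cascade configuration
#'
#' Defaults follow the published cascade: barcodes whose reads are under
#' 10% of their combined potential PCR parents are artifacts; a 100-read
#' detection threshold removes sequencing errors and contamination;
#' clonality requires a (size, complexity) class diversity strictly above
#' 2000 and detection in exactly one embryo of the dataset; biomass
#' quantification is restricted to 5-9-element barcodes (1-3- and
#' 13-element sizes are amplification-biased).
#'
#' @param parent_read_fraction Remove a barcode whose reads are strictly
#'   below this fraction of its combined parents' reads (default 0.10).
#' @param min_reads Keep entries with at least this many reads (default
#'   100).
#' @param min_class_diversity Keep barcodes whose class diversity is
#'   strictly greater than this (default 2000).
#' @param quantifiable_sizes Element counts included in biomass analysis
#'   (default 5:9).
#' @return A `filter_config` list.
#' @export
filter_config <- function(parent_read_fraction = 0.10,
                          min_reads = 100L,
                          min_class_diversity = 2000L,
                          quantifiable_sizes = 5:9) {
  stopifnot(parent_read_fraction >= 0, parent_read_fraction <= 1,
            min_reads >= 0)
  structure(
    list(parent_read_fraction = parent_read_fraction,
         min_reads = as.integer(min_reads),
         min_class_diversity = as.integer(min_class_diversity),
         quantifiable_sizes = as.integer(quantifiable_sizes)),
    class = "filter_config"
  )
}

#' Structure filter
#'
#' Removes keys that do not parse as valid barcodes of the cassette,
#' 1-element barcodes, and the unrecombined reference (limited-diversity
#' classes); recombined full-length barcodes are retained.
#'
#' @param counts Tibble (`sample_id`, `key`, `reads`).
#' @param spec A [cassette_spec()].
#' @return Filtered counts.
#' @export
remove_malformed <- function(counts, spec) {
  ref_key <- canonical_key(make_reference(spec))
  keys <- unique(counts$key)
  ok_struct <- vapply(keys, function(k) {
    !inherits(try(parse_key(k, spec), silent = TRUE), "try-error")
  }, logical(1))
  keep <- keys[ok_struct & barcode_size(keys) > 1L & keys != ref_key]
  dplyr::filter(counts, .data$key %in% keep)
}

# signed-element sets: parent = barcode whose signed-element set strictly
# contains the offspring's (PCR chimeras preserve segment orientations)
signed_set <- function(key) sort(as.integer(regmatches(key, gregexpr("[+-][0-9]+", key))[[1]]))

#' PCR-chimera parent filter
#'
#' Within each library, a barcode is a potential PCR artifact of any
#' barcode whose signed-element set strictly contains its own; it is
#' removed when its reads are strictly below `fraction` of the summed
#' reads of all such potential parents. Applied per sample library.
#'
#' @param counts Tibble (`sample_id`, `key`, `reads`).
#' @param fraction Parent read fraction (default 0.10).
#' @return Filtered counts.
#' @export
pcr_artifact_filter <- function(counts, fraction = 0.10) {
  sets <- lapply(unique(counts$key), signed_set)
  names(sets) <- unique(counts$key)
  out <- lapply(split(counts, counts$sample_id), function(lib) {
    s <- sets[lib$key]
    n <- nrow(lib)
    drop <- logical(n)
    for (b in seq_len(n)) {
      parent_reads <- 0
      has_parent <- FALSE
      for (p in seq_len(n)) {
        if (p == b) next
        if (length(s[[p]]) > length(s[[b]]) && all(s[[b]] %in% s[[p]])) {
          has_parent <- TRUE
          parent_reads <- parent_reads + lib$reads[p]
        }
      }
      if (has_parent && lib$reads[b] < fraction * parent_reads) drop[b] <- TRUE
    }
    lib[!drop, , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Read detection threshold
#'
#' @param counts Tibble (`sample_id`, `key`, `reads`).
#' @param min_reads Keep entries with `reads >= min_reads`.
#' @return Filtered counts.
#' @export
read_threshold <- function(counts, min_reads = 100L) {
  out <- dplyr::filter(counts, .data$reads >= min_reads)
  if (nrow(out) == 0L && nrow(counts) > 0L)
    warning("all entries fell below the read threshold")
  out
}

#' Cell-equivalent normalisation
#'
#' Converts reads to cell-equivalents per sample:
#' `reads * cells_sorted / total_reads`, where `total_reads` is the
#' sample's total assigned reads before filtering (taken from the sample
#' sheet column `total_reads` when present, otherwise supplied via
#' `totals`).
#'
#' @param counts Filtered tibble (`sample_id`, `key`, `reads`).
#' @param samples Sample sheet tibble with `sample_id`, `embryo_id`,
#'   `population`, `cells_sorted` and optionally `total_reads`.
#' @param totals Optional named vector of per-sample total reads
#'   (overrides the sheet).
#' @return Counts joined to sample metadata with a `cell_equiv` column.
#' @export
normalize_reads_per_cell <- function(counts, samples, totals = NULL) {
  if (!is.null(totals)) samples$total_reads <- unname(totals[samples$sample_id])
  if (is.null(samples$total_reads))
    stop("per-sample total_reads needed (sample sheet column or `totals`)")
  used <- unique(counts$sample_id)
  miss <- used[!(used %in% samples$sample_id)]
  if (length(miss))
    stop("samples absent from the sheet: ", paste(miss, collapse = ", "))
  bad <- samples$sample_id[is.na(samples$cells_sorted) | samples$cells_sorted <= 0]
  bad <- intersect(bad, used)
  if (length(bad))
    stop("cells_sorted missing or non-positive for sample(s): ",
         paste(bad, collapse = ", "))
  out <- dplyr::inner_join(counts, samples, by = "sample_id")
  out$cell_equiv <- as.numeric(out$reads) * as.numeric(out$cells_sorted) /
    as.numeric(out$total_reads)
  out
}

#' Clonality filter: class diversity and embryo uniqueness
#'
#' Keeps barcodes that (i) belong to a (size, complexity) class whose
#' diversity is strictly greater than `min_class_diversity` — classes
#' with few possible combinations are likely generated independently in
#' several cells — and (ii) are detected in exactly one embryo within
#' their dataset. Barcodes whose complexity is unknown (beyond the search
#' cap or absent from a depth-bounded table) are excluded and reported.
#'
#' @param matrix Normalised counts (from [normalize_reads_per_cell()])
#'   with `key`, `embryo_id` columns.
#' @param table A `barcode_table` for the cassette.
#' @param min_class_diversity Strict lower bound on class diversity.
#' @param dataset Optional named vector mapping `embryo_id` to a dataset
#'   label; uniqueness is assessed within a dataset (default: all embryos
#'   one dataset).
#' @return The informative subset of `matrix`, with `size`, `complexity`,
#'   `class_diversity` columns added; excluded-for-unknown-complexity keys
#'   in attribute `unknown_complexity`.
#' @export
clonality_filter <- function(matrix, table, min_class_diversity = 2000L,
                             dataset = NULL) {
  if (nrow(matrix) == 0L) return(matrix)
  matrix$size <- barcode_size(matrix$key)
  matrix$complexity <- lookup_complexity(table, matrix$key)
  matrix$class_diversity <- lookup_class_diversity(table, matrix$key)
  unknown <- unique(matrix$key[is.na(matrix$complexity)])
  matrix <- dplyr::filter(matrix, !is.na(.data$complexity),
                          .data$class_diversity > min_class_diversity)
  ds <- if (is.null(dataset)) {
    rep("all", nrow(matrix))
  } else {
    unname(dataset[as.character(matrix$embryo_id)])
  }
  matrix$.dataset <- ds
  n_embryos <- dplyr::summarise(
    dplyr::group_by(matrix, .data$.dataset, .data$key),
    n_embryos = dplyr::n_distinct(.data$embryo_id), .groups = "drop"
  )
  matrix <- dplyr::inner_join(matrix, n_embryos, by = c(".dataset", "key"))
  out <- dplyr::select(
    dplyr::filter(matrix, .data$n_embryos == 1L),
    -".dataset", -"n_embryos"
  )
  attr(out, "unknown_complexity") <- unknown
  out
}

#' Restrict informative barcodes to quantifiable sizes
#'
#' Biomass quantification uses 5-9-element barcodes only; other sizes are
#' retained upstream for presence/outcome analysis but their read
#' frequencies are amplification-biased.
#'
#' @param informative Informative-barcode tibble with a `size` column (or
#'   `key` to derive it).
#' @param sizes Integer set of quantifiable element counts (default 5:9).
#' @return The quantifiable subset.
#' @export
quantifiable_subset <- function(informative, sizes = 5:9) {
  if (!("size" %in% names(informative)))
    informative$size <- barcode_size(informative$key)
  dplyr::filter(informative, .data$size %in% sizes)
}

#' Run the full filtering cascade
#'
#' Structure filter, PCR-chimera parent filter, read threshold,
#' cell-equivalent normalisation, then the clonality (class-diversity +
#' embryo-uniqueness) filter, in that order. Returns the informative
#' barcode matrix plus an audit of which stage removed each barcode.
#'
#' @param counts Raw tibble (`sample_id`, `key`, `reads`).
#' @param samples Sample sheet (see [normalize_reads_per_cell()]).
#' @param table A `barcode_table`.
#' @param config A [filter_config()].
#' @param spec A [cassette_spec()].
#' @param dataset Optional embryo-to-dataset mapping for uniqueness.
#' @return List: `informative` (normalised informative-barcode tibble),
#'   `audit` (tibble `key`, `sample_id`, `stage` of first removal).
#' @export
filter_barcodes <- function(counts, samples, table, config = filter_config(),
                            spec, dataset = NULL) {
  totals <- tapply(counts$reads, counts$sample_id, sum)
  stage <- list()
  note <- function(before, after, what) {
    gone <- dplyr::anti_join(before, after, by = c("sample_id", "key"))
    if (nrow(gone)) {
      gone$stage <- what
      stage[[length(stage) + 1L]] <<- gone[, c("key", "sample_id", "stage")]
    }
  }
  s1 <- remove_malformed(counts, spec);                   note(counts, s1, "structure")
  s2 <- pcr_artifact_filter(s1, config$parent_read_fraction); note(s1, s2, "pcr_artifact")
  s3 <- read_threshold(s2, config$min_reads);             note(s2, s3, "read_threshold")
  s4 <- normalize_reads_per_cell(s3, samples, totals = totals)
  s5 <- clonality_filter(s4, table, config$min_class_diversity, dataset)
  note(s4[, c("sample_id", "key")], s5[, c("sample_id", "key")], "clonality")
  list(informative = s5, audit = dplyr::bind_rows(stage))
}
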