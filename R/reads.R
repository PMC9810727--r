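#' Attach read-simulation sequences to a cassette spec
#'
#' Generates element sequences (pairwise >= 2 mismatches apart in both
#' orientations) and flanking arms for a spec that lacks them, so reads
#' can be simulated and extracted. Uses the current RNG state.
#'
#' @param spec A [cassette_spec()].
#' @param element_length Element length in bp (default 10).
#' @param flank_length Flanking-arm length in bp (default 20).
#' @return The spec with `sequences`, `flank_left`, `flank_right` set.
#' @export
with_read_sequences <- function(spec, element_length = 10L, flank_length = 20L) {
  if (!is.null(spec$sequences) && !is.null(spec$flank_left)) return(spec)
  seqs <- generate_element_sequences(spec$n_elements + 2L,
                                     length = max(element_length, flank_length))
  elements <- substr(seqs[seq_len(spec$n_elements)], 1L, element_length)
  # re-check separation at the trimmed length
  check_element_distances(elements)
  cassette_spec(
    n_elements = spec$n_elements,
    sequences = elements,
    loxp_length = spec$loxp_length,
    min_recomb_distance = spec$min_recomb_distance,
    site_orientations = spec$site_orientations,
    flank_left = substr(seqs[spec$n_elements + 1L], 1L, flank_length),
    flank_right = substr(seqs[spec$n_elements + 2L], 1L, flank_length),
    loxp_sequence = spec$loxp_sequence
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# amplicon sequence of a barcode: left flank, then loxP/element alternation,
# then right flank; inverted elements appear reverse-complemented
amplicon_seq <- function(key, spec) {
  st <- parse_key(key, spec)
  el <- ifelse(st > 0L, spec$sequences[abs(st)], revcomp(spec$sequences[abs(st)]))
  paste0(spec$flank_left,
         paste0(spec$loxp_sequence, el, collapse = ""),
         spec$loxp_sequence, spec$flank_right)
}

#' Write simulated paired-end FASTQ for a counts table
#'
#' Emits `reads` copies of each barcode's amplicon per sample as a
#' multiplexed read pair: read 1 starts with a random 0..`max_stagger` bp
#' stagger then the left flank; read 2 is the reverse complement from the
#' right end; dual indexes are carried in the headers
#' (`... 1:N:0:<index1>+<index2>`). Both mates are truncated to
#' `read_length`; with the default 13-element cassette geometry and 300 bp
#' reads, only full-length barcodes leave one (middle) element uncovered,
#' exercising imputation.
#'
#' @param counts Tibble (`sample_id`, `key`, `reads`).
#' @param samples Sample sheet with `sample_id`, `index1`, `index2`.
#' @param spec A [cassette_spec()] with sequences and flanks.
#' @param fastq1,fastq2 Output paths (gzipped when ending in `.gz`).
#' @param read_length Bases per mate (default 300).
#' @param max_stagger Maximal stagger length (default 7).
#' @param error_rate Per-base substitution probability applied to both
#'   mates (default 0).
#' @return Invisibly, the number of read pairs written.
#' @export
write_cohort_fastq <- function(counts, samples, spec, fastq1, fastq2,
                               read_length = 300L, max_stagger = 7L,
                               error_rate = 0) {
  stopifnot(!is.null(spec$sequences), !is.null(spec$flank_left))
  amp <- vapply(unique(counts$key), amplicon_seq, character(1), spec = spec)
  idx <- stats::setNames(paste0(samples$index1, "+", samples$index2),
                         samples$sample_id)
  n_total <- sum(counts$reads)
  r1 <- character(n_total); r2 <- character(n_total); hd <- character(n_total)
  pos <- 0L
  for (i in seq_len(nrow(counts))) {
    a <- amp[[counts$key[i]]]
    rc_a <- revcomp(a)
    for (k in seq_len(counts$reads[i])) {
      pos <- pos + 1L
      s <- sample.int(max_stagger + 1L, 1L) - 1L
      stag <- if (s > 0L) paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                                collapse = "") else ""
      r1[pos] <- substr(paste0(stag, a), 1L, read_length)
      r2[pos] <- substr(rc_a, 1L, read_length)
      hd[pos] <- sprintf("r%07d 1:N:0:%s", pos, idx[[counts$sample_id[i]]])
    }
  }
  if (error_rate > 0) {
    r1 <- mutate_bases(r1, error_rate)
    r2 <- mutate_bases(r2, error_rate)
  }
  write_fastq_file <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- hd
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(w)
      strrep("I", w), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  }
  write_fastq_file(r1, fastq1)
  write_fastq_file(r2, fastq2)
  invisible(n_total)
}

# uniform random substitutions at the given per-base rate
mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    if (!length(hits)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hits] <- vapply(ch[hits], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
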