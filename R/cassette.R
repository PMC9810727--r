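#' Define a loxP barcoding cassette
#'
#' A cassette is an ordered array of short unique DNA elements interleaved
#' with loxP sites in strictly alternating orientation: `n` elements are
#' flanked by `n + 1` sites, element `i` lying between sites `i` and
#' `i + 1`. Cre recombination between two sites inverts (head-to-head
#' sites) or excises (head-to-tail sites) the intervening segment, but only
#' when the two sites are at least `min_recomb_distance` apart.
#'
#' Element sequences are optional: all recombination and complexity logic
#' depends on element ids and lengths only. Sequences are required for read
#' simulation/extraction and, when given, every pair of elements must
#' differ at >= 2 positions in either orientation so that single-mismatch
#' element calls are unambiguous.
#'
#' @param n_elements Number of elements (default 13, the full cassette).
#' @param element_lengths Integer vector of element lengths in bp, recycled
#'   to `n_elements`. Default 10 bp (design range 8-14 bp).
#' @param sequences Optional character vector of element DNA sequences; when
#'   supplied, lengths are taken from the sequences.
#' @param loxp_length Length of a loxP site in bp (34).
#' @param min_recomb_distance Minimal distance in bp between two loxP sites
#'   for recombination to occur (default 82). Measured as the gap strictly
#'   between the two recombining sites (intervening elements plus
#'   intervening loxP sites), excluding the recombining sites themselves.
#' @param site_orientations Optional orientation vector (`+1`/`-1`) of
#'   length `n_elements + 1`; must strictly alternate. Defaults to
#'   `+1, -1, +1, ...`.
#' @param flank_left,flank_right Optional flanking-arm DNA sequences used
#'   for read simulation and validation.
#' @param loxp_sequence Optional loxP spacer sequence (used only by the read
#'   simulator/extractor as a positional token); defaults to a fixed 34 bp
#'   sequence.
#' @return An object of class `cassette_spec`.
#' @export
cassette_spec <- function(n_elements = 13,
                          element_lengths = 10L,
                          sequences = NULL,
                          loxp_length = 34L,
                          min_recomb_distance = 82L,
                          site_orientations = NULL,
                          flank_left = NULL,
                          flank_right = NULL,
                          loxp_sequence = NULL) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 1L)
    stop("n_elements must be a positive integer")
  if (!is.null(sequences)) {
    if (length(sequences) != n_elements)
      stop("need one sequence per element")
    sequences <- toupper(as.character(sequences))
    if (!all(grepl("^[ACGT]+$", sequences)))
      stop("element sequences must be ACGT strings")
    element_lengths <- nchar(sequences)
    check_element_distances(sequences)
  } else {
    element_lengths <- rep_len(as.integer(element_lengths), n_elements)
  }
  if (any(element_lengths < 1L)) stop("element lengths must be >= 1 bp")
  if (is.null(site_orientations)) {
    site_orientations <- rep_len(c(1L, -1L), n_elements + 1L)
  } else {
    site_orientations <- as.integer(sign(site_orientations))
    if (length(site_orientations) != n_elements + 1L)
      stop("need n_elements + 1 site orientations")
    if (any(site_orientations == 0L))
      stop("site orientations must be +1 or -1")
    if (any(diff(site_orientations) == 0L))
      stop("site orientations must strictly alternate")
  }
  if (is.null(loxp_sequence)) {
    # fixed token standing in for the 34 bp loxP site; half-site sequence
    # identity after recombination is not modelled
    loxp_sequence <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"
  }
  if (nchar(loxp_sequence) != loxp_length)
    stop("loxp_sequence length must equal loxp_length")
  structure(
    list(
      n_elements = n_elements,
      element_lengths = as.integer(element_lengths),
      sequences = sequences,
      loxp_length = as.integer(loxp_length),
      min_recomb_distance = as.integer(min_recomb_distance),
      site_orientations = site_orientations,
      flank_left = flank_left,
      flank_right = flank_right,
      loxp_sequence = loxp_sequence
    ),
    class = "cassette_spec"
  )
}

#' @export
print.cassette_spec <- function(x, ...) {
  cat(sprintf(
    "<cassette_spec> %d elements (%d-%d bp), %d alternating loxP sites, min recombination distance %d bp\n",
    x$n_elements, min(x$element_lengths), max(x$element_lengths),
    x$n_elements + 1L, x$min_recomb_distance
  ))
  invisible(x)
}

# every pair of element sequences must differ at >= 2 positions in both
# orientations (equal-length pairs; unequal lengths can never be confused
# under slot-anchored matching)
check_element_distances <- function(sequences, min_dist = 2L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences)))
  n <- length(sequences)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (nchar(sequences[i]) != nchar(sequences[j])) next
      d_f <- hamming(sequences[i], sequences[j])
      d_r <- hamming(sequences[i], rc[j])
      if (min(d_f, d_r) < min_dist)
        stop(sprintf(
          "elements %d and %d differ by < %d nucleotides in some orientation",
          i, j, min_dist
        ))
    }
  }
  invisible(TRUE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Reference (unrecombined) cassette state
#'
#' A cassette state (a barcode, once detached from the locus) is stored as
#' a signed integer vector: entry `k` is the element id at slot `k`, with
#' sign `+1` for reference-strand orientation and `-1` for inverted.
#' Because the leftmost loxP site survives every legal event and site
#' orientations always alternate, the flanking sites of any reachable state
#' are implied and need not be stored.
#'
#' @param spec A [cassette_spec()].
#' @return Signed integer vector of element ids, the unrecombined state
#'   (complexity 0).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "cassette_spec"))
  seq_len(spec$n_elements)
}

#' Canonical barcode keys
#'
#' `canonical_key()` serialises a state as e.g. `"+1+2-5"`; `parse_key()`
#' inverts it and validates structure (known ids, no duplicates). Keys are
#' unique per distinct state and are the join key in every table the
#' pipeline writes.
#'
#' @param state Signed integer vector of element ids.
#' @param key Character key such as `"+1-3+2"`.
#' @param spec A [cassette_spec()] giving the id universe.
#' @return `canonical_key()` a string; `parse_key()` a signed integer
#'   vector.
#' @export
canonical_key <- function(state) {
  paste0(ifelse(state > 0L, "+", "-"), abs(state), collapse = "")
}

#' @rdname canonical_key
#' @export
parse_key <- function(key, spec) {
  if (length(key) != 1L || !is.character(key))
    stop("key must be a single string")
  if (!grepl("^([+-][0-9]+)+$", key))
    stop("malformed barcode key: ", key)
  tok <- regmatches(key, gregexpr("[+-][0-9]+", key))[[1]]
  state <- as.integer(tok)
  validate_state(state, spec)
  state
}

validate_state <- function(state, spec) {
  ids <- abs(state)
  if (length(state) == 0L) stop("empty state")
  if (any(ids < 1L | ids > spec$n_elements))
    stop("unknown element id in state")
  if (anyDuplicated(ids))
    stop("duplicate element id in state")
  invisible(state)
}

#' Number of elements in a barcode key
#'
#' @param key Character vector of canonical keys.
#' @return Integer vector of element counts.
#' @export
barcode_size <- function(key) {
  lengths(regmatches(key, gregexpr("[+-]", key)))
}

#' Distance between two loxP sites of a state
#'
#' The gap strictly between sites `i` and `j` (1-based, `i < j`, a state
#' with `k` elements has sites `1..k+1`): the lengths of the intervening
#' elements plus one loxP length per intervening site. This is the quantity
#' compared against `min_recomb_distance`; with element lengths in 8-14 bp
#' and 34 bp loxP sites, any gap spanning 1-2 elements is < 82 bp and any
#' spanning >= 3 elements is >= 82 bp, so legal events always move at least
#' 3 elements.
#'
#' @param state Signed integer element vector.
#' @param i,j Site indices, `1 <= i < j <= length(state) + 1`.
#' @param spec A [cassette_spec()].
#' @return Distance in bp.
#' @export
inter_site_distance <- function(state, i, j, spec) {
  n_sites <- length(state) + 1L
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  if (i < 1L || j > n_sites || i == j)
    stop("site indices out of range")
  lens <- spec$element_lengths[abs(state)]
  sum(lens[i:(j - 1L)]) + spec$loxp_length * (j - i - 1L)
}

#' Generate element sequences with guaranteed pairwise separation
#'
#' Draws random DNA sequences of the given length, rejecting candidates
#' within Hamming distance 2 of any accepted sequence in either
#' orientation, so that 1-mismatch element calls are always unambiguous.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (one value; slot-anchored extraction
#'   assumes equal element lengths).
#' @param min_dist Minimal pairwise distance (default 2).
#' @return Character vector of sequences.
#' @export
generate_element_sequences <- function(n, length = 10L, min_dist = 2L) {
  out <- character(0)
  out_codes <- list()
  batches <- 0L
  while (length(out) < n) {
    batches <- batches + 1L
    if (batches > 200L) stop("could not generate separated sequences")
    cand <- vapply(seq_len(2L * n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    cand_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cand)))
    for (i in seq_along(cand)) {
      if (length(out) >= n) break
      cc <- utf8ToInt(cand[i]); cr <- utf8ToInt(cand_rc[i])
      # self-palindromic elements would make orientation calls ambiguous
      if (sum(cc != cr) < min_dist) next
      ok <- all(vapply(out_codes, function(s) {
        min(sum(s != cc), sum(s != cr)) >= min_dist
      }, logical(1)))
      if (ok) {
        out <- c(out, cand[i])
        out_codes[[length(out)]] <- cc
      }
    }
  }
  out
}
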