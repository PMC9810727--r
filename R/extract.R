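#' @importFrom dplyr .data
NULL

# integer code matrix (L x 2n) of element sequences, forward then
# reverse-complement, for fast slot matching
element_matcher <- function(spec) {
  if (is.null(spec$sequences))
    stop("cassette spec carries no element sequences; extraction needs them")
  L <- unique(nchar(spec$sequences))
  if (length(L) != 1L)
    stop("slot-anchored extraction requires equal element lengths")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(spec$sequences)))
  codes <- vapply(c(spec$sequences, rc), utf8ToInt, integer(L))
  n <- spec$n_elements
  list(codes = codes, L = L, n = n,
       id = c(seq_len(n), seq_len(n)),
       orient = c(rep(1L, n), rep(-1L, n)))
}

# unique nearest element (either orientation) within max_mm mismatches;
# ties and misses are no-calls (id NA). Uniqueness at 1 mismatch is
# guaranteed when elements differ pairwise by >= 2 nt in both orientations.
match_slot <- function(slot_seq, matcher, max_mm = 1L) {
  x <- utf8ToInt(slot_seq)
  if (length(x) != matcher$L) return(list(id = NA_integer_, orient = NA_integer_, mm = NA_integer_))
  d <- colSums(matcher$codes != x)
  best <- min(d)
  if (best > max_mm || sum(d == best) > 1L)
    return(list(id = NA_integer_, orient = NA_integer_, mm = NA_integer_))
  w <- which.min(d)
  list(id = matcher$id[w], orient = matcher$orient[w], mm = as.integer(best))
}

str_ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Scan element slots of one mate. `seq` must start at the first loxP site
# (left mate, flank already trimmed) or end at the last loxP site's outer
# edge (right mate: pass the reverse-complemented read, which is a suffix
# of the amplicon ending in the right flank; the flank suffix is trimmed
# here). Returns per-slot calls (relative to the scanned end) and whether
# the opposite flank was reached.
scan_slots <- function(seq, spec, matcher, side = c("left", "right"),
                       max_mm = 1L, max_loxp_mm = 2L) {
  side <- match.arg(side)
  L <- matcher$L
  lox <- spec$loxp_sequence
  lw <- spec$loxp_length
  other_flank <- if (side == "left") spec$flank_right else spec$flank_left
  calls <- list()
  reached <- FALSE
  if (side == "right") {
    fr <- spec$flank_right
    w <- min(nchar(fr), nchar(seq))
    if (w < 6L || str_ham(substr(seq, nchar(seq) - w + 1L, nchar(seq)),
                          substr(fr, nchar(fr) - w + 1L, nchar(fr))) > 1L)
      return(NULL)  # right flank missing: reject mate
    seq <- substr(seq, 1L, nchar(seq) - w)
  }
  pos <- if (side == "left") 1L else nchar(seq)
  repeat {
    # loxP spacer token
    if (side == "left") {
      if (nchar(seq) - pos + 1L < lw) break
      tok <- substr(seq, pos, pos + lw - 1L)
    } else {
      if (pos < lw) break
      tok <- substr(seq, pos - lw + 1L, pos)
    }
    if (str_ham(tok, lox) > max_loxp_mm) break
    # opposite flank => cassette fully traversed
    if (side == "left") {
      after <- pos + lw
      w <- min(nchar(other_flank), nchar(seq) - after + 1L)
      if (w >= 6L &&
          str_ham(substr(seq, after, after + w - 1L),
                  substr(other_flank, 1L, w)) <= 1L) {
        reached <- TRUE
        break
      }
      if (nchar(seq) - after + 1L < L) break
      slot <- substr(seq, after, after + L - 1L)
      pos <- after + L
    } else {
      before <- pos - lw
      w <- min(nchar(other_flank), before)
      if (w >= 6L &&
          str_ham(substr(seq, before - w + 1L, before),
                  substr(other_flank, nchar(other_flank) - w + 1L, nchar(other_flank))) <= 1L) {
        reached <- TRUE
        break
      }
      if (before < L) break
      slot <- substr(seq, before - L + 1L, before)
      pos <- before - L
    }
    calls[[length(calls) + 1L]] <- match_slot(slot, matcher, max_mm)
  }
  id <- vapply(calls, `[[`, integer(1), "id")
  orient <- vapply(calls, `[[`, integer(1), "orient")
  mm <- vapply(calls, `[[`, integer(1), "mm")
  list(id = id, orient = orient, mm = mm, reached_flank = reached)
}

#' Call cassette elements in a read pair
#'
#' Elements sit at stereotyped positions: 34 bp loxP spacers alternate with
#' fixed-length element slots between the two flanking arms. Slots are
#' scanned from the left flank inward on read 1 and from the right flank
#' inward on the reverse-complemented read 2; each slot is matched against
#' every element sequence in both orientations and called as the unique
#' nearest within `max_mm` mismatches (no-call otherwise).
#'
#' @param read1,read2 Character, one mate pair (read 2 as sequenced, i.e.
#'   reverse strand).
#' @param spec A [cassette_spec()] with `sequences`, `flank_left`,
#'   `flank_right`.
#' @param max_stagger Left flank is searched within the first `max_stagger`
#'   offsets of read 1 (library stagger).
#' @param max_mm Per-element mismatch tolerance (default 1; unambiguous
#'   because elements differ pairwise by >= 2 nt in either orientation).
#' @return List with per-mate slot calls (`left`, `right`, each as from the
#'   internal scanner) or `NULL` when a flank could not be located.
#' @export
locate_elements <- function(read1, read2, spec, max_stagger = 7L, max_mm = 1L) {
  matcher <- element_matcher(spec)
  fl <- spec$flank_left
  lfl <- nchar(fl)
  off <- NA_integer_
  for (o in 0:max_stagger) {
    if (o + lfl > nchar(read1)) break
    if (str_ham(substr(read1, o + 1L, o + lfl), fl) <= 1L) { off <- o; break }
  }
  if (is.na(off)) return(NULL)
  left <- scan_slots(substr(read1, off + lfl + 1L, nchar(read1)),
                     spec, matcher, "left", max_mm)
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read2)))
  right <- scan_slots(rc2, spec, matcher, "right", max_mm)
  if (is.null(right)) return(NULL)
  list(left = left, right = right)
}

#' Assemble a barcode from the two mates' element calls
#'
#' Merges left-anchored and right-anchored slot calls. If either mate
#' traversed the whole cassette the slot count is known directly;
#' otherwise every odd candidate slot count up to the cassette size is
#' tried (reachable barcodes have odd element counts) and the read is
#' kept only when exactly one count gives a consistent merge. A single
#' uncovered middle slot is tolerated only at full length (the paired
#' read span covers any shorter amplicon completely), to be filled by
#' [impute_middle()]. Conflicting calls at a shared slot, duplicate
#' element ids, interior no-calls, or ambiguous lengths reject the read.
#'
#' @param loc Result of [locate_elements()].
#' @param spec A [cassette_spec()].
#' @return List: `status` (`"complete"`, `"needs_imputation"`, or
#'   `"rejected"`), `state` (signed id vector, `NA` at the missing slot
#'   when imputation is needed), `reason` for rejections.
#' @export
assemble_barcode <- function(loc, spec) {
  rej <- function(reason) list(status = "rejected", state = NULL, reason = reason)
  if (is.null(loc)) return(rej("flank_not_found"))
  l <- loc$left; r <- loc$right
  a <- length(l$id); b <- length(r$id)
  if (l$reached_flank || r$reached_flank) {
    cand_k <- unique(c(if (l$reached_flank) a, if (r$reached_flank) b))
    if (length(cand_k) > 1L) return(rej("mate_conflict"))
  } else {
    cand_k <- seq.int(max(a, b, 1L), spec$n_elements)
    cand_k <- cand_k[cand_k %% 2L == 1L | cand_k == spec$n_elements]
  }
  try_k <- function(k) {
    if (a > k || b > k) return(NULL)
    slots <- matrix(NA_integer_, nrow = 2L, ncol = k)
    if (a > 0L) slots[1L, seq_len(a)] <- l$id * l$orient
    if (b > 0L) slots[2L, k - seq_len(b) + 1L] <- r$id * r$orient
    merged <- integer(k)
    for (s in seq_len(k)) {
      v <- slots[, s]
      v <- v[!is.na(v)]
      if (length(v) == 0L) { merged[s] <- NA_integer_; next }
      if (length(unique(v)) > 1L) return(NULL)   # mate conflict at slot
      merged[s] <- v[1L]
    }
    ids <- abs(merged[!is.na(merged)])
    if (anyDuplicated(ids)) return(NULL)
    miss <- which(is.na(merged))
    if (length(miss) == 0L) return(list(status = "complete", state = merged))
    if (length(miss) == 1L && k == spec$n_elements &&
        length(ids) == spec$n_elements - 1L)
      return(list(status = "needs_imputation", state = merged))
    NULL
  }
  hits <- Filter(Negate(is.null), lapply(cand_k, try_k))
  if (length(hits) == 0L) return(rej("no_consistent_assembly"))
  if (length(hits) > 1L) return(rej("ambiguous_length"))
  c(hits[[1]], list(reason = NA_character_))
}

#' Impute the uncovered middle element of a full-length barcode
#'
#' Paired-end reads of full-length cassettes cover all but one middle
#' slot. The missing element's identity is the single absent id; its
#' orientation is chosen as the candidate whose completed barcode has the
#' smaller recombination complexity (minimal-steps assumption). Equal
#' complexities (or both beyond the search cap) flag the barcode
#' ambiguous.
#'
#' @param state Signed id vector with exactly one `NA` slot and all other
#'   ids distinct.
#' @param spec A [cassette_spec()].
#' @param table Optional `barcode_table` for exact complexity lookup.
#' @param max_depth Complexity search cap when no table is given.
#' @param cache Optional environment memoising candidate complexities
#'   across reads.
#' @return List: `state` (completed, or `NULL`), `ambiguous` (logical).
#' @export
impute_middle <- function(state, spec, table = NULL, max_depth = 4L,
                          cache = NULL) {
  miss <- which(is.na(state))
  stopifnot(length(miss) == 1L)
  absent <- setdiff(seq_len(spec$n_elements), abs(state[-miss]))
  stopifnot(length(absent) == 1L)
  cand <- list(state, state)
  cand[[1]][miss] <- absent
  cand[[2]][miss] <- -absent
  keys <- vapply(cand, canonical_key, character(1))
  cx <- NULL
  if (!is.null(cache)) cx <- cache[[paste(keys, collapse = " ")]]
  if (is.null(cx)) {
    cx <- complexity_of(keys, spec, table = table, max_depth = max_depth)
    if (!is.null(cache)) cache[[paste(keys, collapse = " ")]] <- cx
  }
  cx[is.infinite(cx)] <- NA_real_
  if (all(is.na(cx)) || (!anyNA(cx) && cx[1] == cx[2]))
    return(list(state = NULL, ambiguous = TRUE))
  pick <- if (anyNA(cx)) which(!is.na(cx)) else which.min(cx)
  list(state = cand[[pick]], ambiguous = FALSE)
}

#' Assign read pairs to samples by dual index
#'
#' Indexes are read from the FASTQ header (`...:<index1>+<index2>` suffix).
#' A pair is assigned to the sample at minimal combined index distance if
#' that distance is at most `max_index_mismatch` and the minimum is
#' unique; equidistant pairs are left unassigned.
#'
#' @param headers Character vector of read-1 headers.
#' @param samples Sample sheet tibble with `sample_id`, `index1`, `index2`.
#' @param max_index_mismatch Combined mismatch tolerance (default 1).
#' @return Character vector of `sample_id` (NA for unassigned), parallel to
#'   `headers`.
#' @export
demultiplex <- function(headers, samples, max_index_mismatch = 1L) {
  if (anyDuplicated(paste(samples$index1, samples$index2)))
    stop("duplicate index pairs in the sample sheet")
  m <- regmatches(headers, regexec("([ACGTN]+)\\+([ACGTN]+)$", headers))
  i1 <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, character(1))
  i2 <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, character(1))
  s1 <- vapply(samples$index1, utf8ToInt, integer(nchar(samples$index1[1])))
  s2 <- vapply(samples$index2, utf8ToInt, integer(nchar(samples$index2[1])))
  vapply(seq_along(headers), function(r) {
    if (is.na(i1[r])) return(NA_character_)
    d <- colSums(s1 != utf8ToInt(i1[r])) + colSums(s2 != utf8ToInt(i2[r]))
    best <- min(d)
    if (best > max_index_mismatch || sum(d == best) > 1L) return(NA_character_)
    samples$sample_id[which.min(d)]
  }, character(1))
}

#' Tally extracted barcodes per sample
#'
#' @param sample_id,keys Parallel character vectors, one entry per accepted
#'   read.
#' @return Tibble (`sample_id`, `key`, `reads`) with exact tallies.
#' @export
count_barcodes <- function(sample_id, keys) {
  dplyr::count(tibble::tibble(sample_id = sample_id, key = keys),
               .data$sample_id, .data$key, name = "reads")
}

#' Extract per-sample barcode counts from paired FASTQ
#'
#' Full extraction pipeline: demultiplex by dual index, call elements in
#' both mates, assemble and (for full-length barcodes) impute the middle
#' element, and tally canonical keys per sample.
#'
#' @param fastq1,fastq2 Paths to the paired (optionally gzipped) FASTQ
#'   files.
#' @param samples Sample sheet tibble (`sample_id`, `index1`, `index2`,
#'   ...).
#' @param spec A [cassette_spec()] with element and flank sequences.
#' @param table Optional `barcode_table` (exact imputation complexities).
#' @param max_index_mismatch,max_mm,max_stagger See [demultiplex()] and
#'   [locate_elements()].
#' @param impute_max_depth Complexity search cap for imputation.
#' @return List: `counts` tibble (`sample_id`, `key`, `reads`), `qc` tibble
#'   of per-sample read tallies (assigned, accepted, imputed, ambiguous,
#'   rejected), plus `unassigned` read count.
#' @export
extract_counts <- function(fastq1, fastq2, samples, spec, table = NULL,
                           max_index_mismatch = 1L, max_mm = 1L,
                           max_stagger = 7L, impute_max_depth = 4L) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  sample_of <- demultiplex(names(r1), samples, max_index_mismatch)
  seq1 <- as.character(r1)
  seq2 <- as.character(r2)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(r1))
  status <- character(length(r1))
  for (i in seq_along(seq1)) {
    if (is.na(sample_of[i])) { status[i] <- "unassigned"; next }
    loc <- locate_elements(seq1[i], seq2[i], spec, max_stagger, max_mm)
    asm <- assemble_barcode(loc, spec)
    if (asm$status == "rejected") { status[i] <- "rejected"; next }
    st <- asm$state
    if (asm$status == "needs_imputation") {
      imp <- impute_middle(st, spec, table = table,
                           max_depth = impute_max_depth, cache = cache)
      if (imp$ambiguous) { status[i] <- "ambiguous"; next }
      st <- imp$state
      status[i] <- "imputed"
    } else {
      status[i] <- "accepted"
    }
    rows[[i]] <- c(sample_of[i], canonical_key(st))
  }
  ok <- !vapply(rows, is.null, logical(1))
  counts <- if (any(ok)) {
    df <- do.call(rbind, rows[ok])
    dplyr::count(
      tibble::tibble(sample_id = df[, 1], key = df[, 2]),
      .data$sample_id, .data$key, name = "reads"
    )
  } else {
    tibble::tibble(sample_id = character(), key = character(),
                   reads = integer())
  }
  qc <- dplyr::count(
    tibble::tibble(sample_id = ifelse(is.na(sample_of), "<unassigned>", sample_of),
                   status = status),
    .data$sample_id, .data$status, name = "reads"
  )
  list(counts = counts, qc = qc,
       unassigned = sum(is.na(sample_of)))
}
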