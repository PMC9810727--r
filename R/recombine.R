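#' Legal recombination events on a cassette state
#'
#' Enumerates all pairs of loxP sites whose gap (elements plus intervening
#' loxP sites strictly between them) is at least
#' `spec$min_recomb_distance`. Because site orientations strictly
#' alternate, a pair spanning an odd number of elements joins opposite-
#' orientation sites and inverts the intervening segment; an even span
#' joins same-orientation sites and excises it. Distances are recomputed on
#' the state at hand, not the reference geometry.
#'
#' @param state Signed integer element vector.
#' @param spec A [cassette_spec()].
#' @return A data.frame with columns `site_a`, `site_b` (1-based,
#'   `site_a < site_b`), `kind` (`"inversion"`/`"excision"`) and
#'   `distance` (bp), ordered by `site_a` then `site_b`.
#' @export
valid_events <- function(state, spec) {
  validate_state(state, spec)
  n <- length(state)
  n_sites <- n + 1L
  cum <- c(0L, cumsum(spec$element_lengths[abs(state)]))
  pairs <- which(upper.tri(matrix(0, n_sites, n_sites)), arr.ind = TRUE)
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  dist <- cum[j - 1L + 1L] - cum[i - 1L + 1L] + spec$loxp_length * (j - i - 1L)
  keep <- dist >= spec$min_recomb_distance
  i <- i[keep]; j <- j[keep]; dist <- dist[keep]
  kind <- ifelse((j - i) %% 2L == 1L, "inversion", "excision")
  ord <- order(i, j)
  data.frame(
    site_a = i[ord], site_b = j[ord],
    kind = kind[ord], distance = dist[ord],
    stringsAsFactors = FALSE
  )
}

#' Apply a recombination event to a state
#'
#' Inversion: the elements strictly between the two sites are
#' order-reversed and orientation-flipped; the recombining sites are
#' unchanged. Excision: those elements are deleted and the two (same-
#' orientation) sites merge into one. Both preserve site-orientation
#' alternation and element uniqueness.
#'
#' @param state Signed integer element vector.
#' @param site_a,site_b Site indices of the event (`site_a < site_b`).
#' @param kind `"inversion"` or `"excision"`.
#' @param spec A [cassette_spec()]; used to check the event is legal.
#' @param check Set `FALSE` to skip the legality check (internal hot
#'   paths).
#' @return The recombined state.
#' @export
apply_event <- function(state, site_a, site_b, kind = c("inversion", "excision"),
                        spec = NULL, check = TRUE) {
  kind <- match.arg(kind)
  n <- length(state)
  if (site_a >= site_b || site_a < 1L || site_b > n + 1L)
    stop("invalid site pair")
  span_odd <- (site_b - site_a) %% 2L == 1L
  if (check) {
    if (span_odd != (kind == "inversion"))
      stop("event kind inconsistent with site orientations")
    if (!is.null(spec) &&
        inter_site_distance(state, site_a, site_b, spec) < spec$min_recomb_distance)
      stop("sites closer than the minimal recombination distance")
  }
  idx <- site_a:(site_b - 1L)
  if (kind == "inversion") {
    state[idx] <- -rev(state[idx])
    state
  } else {
    state[-idx]
  }
}

#' Enumerate all barcodes reachable from the reference
#'
#' Breadth-first closure of the recombination state space under the
#' distance rule, generation-synchronous so that the generation at which a
#' barcode first appears is its complexity (minimal number of
#' recombination events). The closure of the full 13-element cassette is
#' astronomically large (>3e10 barcodes); a resource guard refuses
#' unbounded builds of large cassettes unless `allow_large` is set, and
#' any build aborts beyond `max_states` states.
#'
#' @param spec A [cassette_spec()].
#' @param max_depth Maximal complexity to build, or `Inf` for the full
#'   closure (fixed point).
#' @param max_states Hard cap on table size.
#' @param allow_large Permit unbounded builds of cassettes with more than 9
#'   elements.
#' @return A `barcode_table`: list with `key`, `complexity`, `size`
#'   (parallel vectors over all reachable barcodes), `class_index` (tibble
#'   of per-(size, complexity) diversities), `closed` (TRUE if the build
#'   reached the fixed point, i.e. diversities are exact), and
#'   `max_depth_built`.
#' @export
enumerate_reachable <- function(spec, max_depth = Inf, max_states = 5e6,
                                allow_large = FALSE) {
  stopifnot(inherits(spec, "cassette_spec"))
  if (is.infinite(max_depth) && spec$n_elements > 9L && !allow_large)
    stop(
      "unbounded closure of a ", spec$n_elements, "-element cassette is ",
      "cluster-scale; pass allow_large = TRUE (and a max_states you can ",
      "afford) or bound max_depth"
    )
  res <- cpp_enumerate(
    spec$element_lengths, spec$loxp_length, spec$min_recomb_distance,
    if (is.infinite(max_depth)) -1L else as.integer(max_depth),
    max_states, integer(0), character(0), FALSE
  )
  class_index <- dplyr::count(
    tibble::tibble(size = res$size, complexity = res$complexity),
    .data$size, .data$complexity,
    name = "diversity"
  )
  structure(
    list(
      key = res$key, complexity = res$complexity, size = res$size,
      class_index = class_index, closed = res$closed,
      max_depth_built = res$max_depth_built, n_elements = spec$n_elements
    ),
    class = "barcode_table"
  )
}

#' @export
print.barcode_table <- function(x, ...) {
  cat(sprintf(
    "<barcode_table> %d-element cassette: %s barcodes, max complexity %d (%s)\n",
    x$n_elements, format(length(x$key), big.mark = ","), x$max_depth_built,
    if (x$closed) "closed: diversities exact" else "depth-bounded: diversities approximate"
  ))
  invisible(x)
}

#' Look up complexities and class diversities in a barcode table
#'
#' @param table A `barcode_table`.
#' @param keys Character vector of canonical keys.
#' @return `lookup_complexity()`: integer complexities (`NA` for keys not
#'   in the table). `lookup_class_diversity()`: integer diversities of each
#'   key's (size, complexity) class (`NA` when the key is absent).
#' @export
lookup_complexity <- function(table, keys) {
  stopifnot(inherits(table, "barcode_table"))
  table$complexity[match(keys, table$key)]
}

#' @rdname lookup_complexity
#' @export
lookup_class_diversity <- function(table, keys) {
  stopifnot(inherits(table, "barcode_table"))
  idx <- match(keys, table$key)
  cls <- paste(table$size[idx], table$complexity[idx])
  ci <- table$class_index
  ci$diversity[match(cls, paste(ci$size, ci$complexity))]
}

#' Minimal recombination complexity of observed barcodes
#'
#' Returns the minimal number of recombination events needed to build each
#' barcode from the reference. With a closed `table` this is an exact
#' lookup (absent keys are unreachable, reported `Inf`). Without a table a
#' targeted breadth-first search is run, expanding only states that retain
#' every element id of the targets (an excision that loses a needed id can
#' never lead to it); barcodes not found within `max_depth` are `NA`
#' ("> max_depth", a lower bound).
#'
#' @param keys Character vector of canonical barcode keys. When searching
#'   without a table all keys must share one element-id set (call per
#'   barcode otherwise).
#' @param spec A [cassette_spec()].
#' @param table Optional `barcode_table` for exact lookup.
#' @param max_depth Search depth cap (default 8).
#' @param max_states Hard cap on search size.
#' @return Numeric vector: complexity, `Inf` (proven unreachable), or `NA`
#'   (not found within `max_depth`).
#' @export
complexity_of <- function(keys, spec, table = NULL, max_depth = 8L,
                          max_states = 5e6) {
  states <- lapply(keys, parse_key, spec = spec)
  if (!is.null(table)) {
    cx <- as.numeric(lookup_complexity(table, keys))
    if (table$closed) cx[is.na(cx)] <- Inf
    return(cx)
  }
  ids <- lapply(states, function(s) sort(abs(s)))
  if (length(unique(vapply(ids, paste, character(1), collapse = ","))) > 1L)
    return(vapply(keys, function(k) {
      complexity_of(k, spec, table = NULL, max_depth = max_depth,
                    max_states = max_states)
    }, numeric(1), USE.NAMES = FALSE))
  res <- cpp_enumerate(
    spec$element_lengths, spec$loxp_length, spec$min_recomb_distance,
    as.integer(max_depth), max_states, ids[[1]], keys, TRUE
  )
  as.numeric(res$target_depth)
}

#' Sample a random recombination path
#'
#' Applies `n_events` uniformly random legal events in sequence, stopping
#' early if no legal event remains. Used by the synthetic-cohort generator
#' to emulate Cre exposure; low event counts concentrate probability on
#' low-complexity barcodes, which therefore recur across embryos.
#'
#' @param spec A [cassette_spec()].
#' @param n_events Number of recombination events to apply.
#' @param state Starting state (default the reference).
#' @return The resulting state (signed integer vector). Randomness comes
#'   from R's RNG; seed with [set.seed()].
#' @export
sample_recombination_path <- function(spec, n_events, state = make_reference(spec)) {
  stopifnot(n_events >= 0)
  lens <- spec$element_lengths
  loxp <- spec$loxp_length
  min_d <- spec$min_recomb_distance
  for (k in seq_len(n_events)) {
    n <- length(state)
    ns <- n + 1L
    cum <- c(0L, cumsum(lens[abs(state)]))
    ij <- which(upper.tri(matrix(FALSE, ns, ns)), arr.ind = TRUE)
    d <- cum[ij[, 2L]] - cum[ij[, 1L]] + loxp * (ij[, 2L] - ij[, 1L] - 1L)
    ok <- which(d >= min_d)
    if (length(ok) == 0L) break
    pick <- ok[sample.int(length(ok), 1L)]
    a <- ij[pick, 1L]; b <- ij[pick, 2L]
    idx <- a:(b - 1L)
    if ((b - a) %% 2L == 1L) {
      state[idx] <- -rev(state[idx])
    } else {
      state <- state[-idx]
    }
  }
  state
}
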