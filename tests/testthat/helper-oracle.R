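# Independent naive oracle for the recombination closure: states carry
# explicit site-orientation vectors and element records, rewriting rules
# are applied literally, and BFS generations define complexity. Kept
# deliberately separate from the package's representation (which stores
# signed element vectors only and infers sites from parity).

oracle_state_key <- function(st) {
  paste(
    paste(st$sites, collapse = ""),
    paste(ifelse(st$orient > 0, "+", "-"), st$id, collapse = ","),
    sep = "|"
  )
}

oracle_elem_key <- function(st) {
  if (length(st$id) == 0L) return("")
  paste0(ifelse(st$orient > 0, "+", "-"), st$id, collapse = "")
}

oracle_initial <- function(n_elements, lengths) {
  list(
    sites = rep_len(c("F", "R"), n_elements + 1L),
    id = seq_len(n_elements),
    orient = rep(1L, n_elements),
    len = rep_len(lengths, n_elements)
  )
}

oracle_children <- function(st, loxp_len, min_dist) {
  n <- length(st$id)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq.int(i + 1L, n + 1L)) {
      gap_elems <- i:(j - 1L)
      d <- sum(st$len[gap_elems]) + loxp_len * (j - i - 1L)
      if (d < min_dist) next
      if (st$sites[i] != st$sites[j]) {
        # inversion: flip and reverse elements i..j-1 and interior sites
        ns <- st
        ns$id[gap_elems] <- rev(st$id[gap_elems])
        ns$orient[gap_elems] <- rev(-st$orient[gap_elems])
        ns$len[gap_elems] <- rev(st$len[gap_elems])
        if (j - i >= 2L) {
          interior <- (i + 1L):(j - 1L)
          ns$sites[interior] <- rev(ifelse(st$sites[interior] == "F", "R", "F"))
        }
        out[[length(out) + 1L]] <- ns
      } else {
        # excision: drop elements i..j-1, merge sites i and j
        ns <- list(
          sites = st$sites[-((i + 1L):j)],
          id = st$id[-gap_elems],
          orient = st$orient[-gap_elems],
          len = st$len[-gap_elems]
        )
        out[[length(out) + 1L]] <- ns
      }
    }
  }
  out
}

oracle_check_state <- function(st) {
  stopifnot(length(st$sites) == length(st$id) + 1L)
  if (length(st$sites) > 1L)
    stopifnot(all(st$sites[-1L] != st$sites[-length(st$sites)]))
  stopifnot(!anyDuplicated(st$id))
}

# full BFS closure; returns element-key -> complexity
oracle_closure <- function(n_elements, lengths = 10L, loxp_len = 34L,
                           min_dist = 82L, max_depth = Inf) {
  seen <- new.env(parent = emptyenv())
  elem_cx <- new.env(parent = emptyenv())
  st0 <- oracle_initial(n_elements, lengths)
  assign(oracle_state_key(st0), 0L, envir = seen)
  assign(oracle_elem_key(st0), 0L, envir = elem_cx)
  frontier <- list(st0)
  depth <- 0L
  while (length(frontier) > 0L && depth < max_depth) {
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) {
      for (ch in oracle_children(st, loxp_len, min_dist)) {
        oracle_check_state(ch)
        k <- oracle_state_key(ch)
        if (is.null(seen[[k]])) {
          seen[[k]] <- depth
          ek <- oracle_elem_key(ch)
          if (is.null(elem_cx[[ek]])) elem_cx[[ek]] <- depth
          nxt[[length(nxt) + 1L]] <- ch
        }
      }
    }
    frontier <- nxt
  }
  out <- unlist(as.list(elem_cx))
  out[order(names(out))]
}
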