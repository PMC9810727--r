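test_that("event enumeration on the full cassette matches the distance rule", {
  sp <- spec13()
  ev <- valid_events(make_reference(sp), sp)
  # brute force over all 91 site pairs with the distance formula
  expect_equal(nrow(ev), 66L)
  expect_equal(sum(ev$kind == "inversion"), 36L)
  expect_equal(sum(ev$kind == "excision"), 30L)
  expect_true(all(ev$distance >= sp$min_recomb_distance))
  expect_gte(min(ev$site_b - ev$site_a), 3L)
  expect_equal(min((ev$site_b - ev$site_a)[ev$kind == "excision"]), 4L)
  # deterministic ordering
  expect_true(!is.unsorted(ev$site_a))
})

test_that("no event is legal on a 1-element cassette under the default rule", {
  sp <- cassette_spec(1, element_lengths = 14)
  expect_equal(nrow(valid_events(make_reference(sp), sp)), 0L)
})

test_that("3-element cassette at distance 0 recombines by site-orientation parity", {
  sp <- cassette_spec(3, min_recomb_distance = 0)
  ev <- valid_events(make_reference(sp), sp)
  expect_true(any(ev$site_a == 1 & ev$site_b == 4 & ev$kind == "inversion"))
  expect_true(any(ev$site_a == 1 & ev$site_b == 3 & ev$kind == "excision"))
  # odd spans inversions, even spans excisions, everywhere
  expect_true(all(((ev$site_b - ev$site_a) %% 2 == 1) ==
                    (ev$kind == "inversion")))
})

test_that("applying events rewrites states correctly", {
  sp <- spec13()
  ref <- make_reference(sp)
  flipped <- apply_event(ref, 1, 14, "inversion", sp)
  expect_identical(flipped, -(13:1))
  expect_identical(apply_event(flipped, 1, 14, "inversion", sp), ref)
  expect_identical(apply_event(ref, 1, 5, "excision", sp), 5:13)
  sp3 <- cassette_spec(3, min_recomb_distance = 0)
  expect_identical(apply_event(make_reference(sp3), 1, 3, "excision", sp3), 3L)
  expect_error(apply_event(ref, 1, 3, "inversion", sp), "inconsistent")
  expect_error(apply_event(ref, 1, 2, "excision", sp), "inconsistent")
})

test_that("tiny closures are exact", {
  tb <- enumerate_reachable(cassette_spec(1, min_recomb_distance = 0))
  expect_setequal(tb$key, c("+1", "-1"))
  expect_equal(tb$complexity[match(c("+1", "-1"), tb$key)], c(0L, 1L))
  expect_true(tb$closed)
  tb3 <- enumerate_reachable(cassette_spec(3, min_recomb_distance = 0))
  # the middle element can never be isolated: adjacent sites are opposite-
  # oriented, so no excision removes exactly one element
  expect_false("+2" %in% tb3$key)
  expect_false("-2" %in% tb3$key)
  expect_true("+3" %in% tb3$key)
  expect_equal(tb3$complexity[tb3$key == "+3"], 1L)
  expect_true(all(tb3$size %% 2 == 1))
})

test_that("closures equal the independent string-rewriting oracle", {
  for (n in c(1L, 3L)) {
    for (md in c(0L, 82L)) {
      tb <- enumerate_reachable(cassette_spec(n, min_recomb_distance = md))
      got <- stats::setNames(tb$complexity, tb$key)
      got <- got[order(names(got))]
      want <- oracle_closure(n, lengths = 10L, min_dist = md)
      expect_identical(got, want, label = sprintf("n=%d min=%d", n, md))
    }
  }
})

test_that("complexity queries agree with the closure and flag unreachables", {
  sp <- spec7()
  tb <- table7()
  expect_equal(complexity_of(canonical_key(make_reference(sp)), sp, tb), 0)
  expect_equal(complexity_of(canonical_key(-(7:1)), sp, tb), 1)
  sp3 <- cassette_spec(3, min_recomb_distance = 0)
  tb3 <- enumerate_reachable(sp3)
  expect_identical(complexity_of("-2", sp3, tb3), Inf)
  # table-free targeted search agrees with the closure
  keys <- tb$key[seq(5, length(tb$key), by = 997)]
  expect_equal(complexity_of(keys, sp, max_depth = 10),
               as.numeric(lookup_complexity(tb, keys)))
  # beyond-cap searches report NA rather than a wrong value
  deep <- tb$key[tb$complexity == 9][1]
  expect_true(is.na(complexity_of(deep, sp, max_depth = 3)))
})

test_that("random paths are seeded, reproducible, and land on legal states", {
  sp <- spec13()
  set.seed(7)
  a <- sample_recombination_path(sp, 5)
  set.seed(7)
  b <- sample_recombination_path(sp, 5)
  expect_identical(a, b)
  expect_identical(sample_recombination_path(sp, 0), make_reference(sp))
  # invariants preserved along many random paths
  set.seed(42)
  for (i in 1:300) {
    st <- sample_recombination_path(sp, sample(1:8, 1))
    expect_equal(anyDuplicated(abs(st)), 0L)
    expect_equal(length(st) %% 2L, 1L)
  }
})

test_that("single events cover exactly the complexity-1 stratum, roughly uniformly", {
  sp <- spec13()
  tb1 <- enumerate_reachable(sp, max_depth = 1)
  stratum <- tb1$key[tb1$complexity == 1L]
  expect_equal(length(stratum), 66L)
  set.seed(123)
  draws <- replicate(6000, canonical_key(sample_recombination_path(sp, 1)))
  expect_setequal(unique(draws), stratum)
  tabulated <- table(draws)
  # uniform within Monte Carlo error: expected ~91 draws per event
  expect_gt(stats::chisq.test(tabulated)$p.value, 1e-4)
})

test_that("excisions shrink states by an even count >= 4 under the default rule", {
  sp <- spec13()
  set.seed(99)
  for (i in 1:100) {
    st <- sample_recombination_path(sp, sample(0:4, 1))
    ev <- valid_events(st, sp)
    exc <- ev[ev$kind == "excision", , drop = FALSE]
    for (r in seq_len(nrow(exc))) {
      child <- apply_event(st, exc$site_a[r], exc$site_b[r], "excision", sp)
      drop <- length(st) - length(child)
      expect_gte(drop, 4L)
      expect_equal(drop %% 2L, 0L)
    }
    inv <- ev[ev$kind == "inversion", , drop = FALSE]
    if (nrow(inv)) {
      r <- sample.int(nrow(inv), 1)
      child <- apply_event(st, inv$site_a[r], inv$site_b[r], "inversion", sp)
      expect_identical(apply_event(child, inv$site_a[r], inv$site_b[r],
                                   "inversion", sp), st)
    }
  }
})

test_that("unbounded builds of large cassettes require explicit opt-in", {
  expect_error(enumerate_reachable(spec13(), max_depth = Inf), "allow_large")
})
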