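# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

spec7 <- function() {
  if (is.null(.fix$spec7)) .fix$spec7 <- cassette_spec(n_elements = 7)
  .fix$spec7
}

table7 <- function() {
  if (is.null(.fix$table7))
    .fix$table7 <- enumerate_reachable(spec7(), max_depth = Inf)
  .fix$table7
}

spec13 <- function() {
  if (is.null(.fix$spec13)) .fix$spec13 <- cassette_spec(n_elements = 13)
  .fix$spec13
}

# noise-free small cohort configuration (no chimeras, errors, bias, PCR
# noise); read depth scaled down for speed
noise_free_config <- function(n_embryos = 3L, n_precursors = 40L, ...) {
  cohort_config(
    n_embryos = n_embryos, n_precursors = n_precursors,
    pcr_noise_sd = 0, chimera_rate = 0, error_barcode_rate = 0,
    size_bias = 1, ...
  )
}

# one-population sample sheet over the given embryos, constant depth
flat_sheet <- function(embryos, population = "EryP", cells = 10000L,
                       total = 100000L) {
  tibble::tibble(
    sample_id = paste0(embryos, "_", population),
    embryo_id = embryos,
    population = population,
    cells_sorted = cells,
    total_reads = total
  )
}

# A 12-barcode fixture exercising every filter rule at its boundary:
# structure (reference, 1-element, malformed), PCR parent fraction
# (149/1500 removed vs 150/1500 kept), read threshold (99 vs 100),
# class diversity, and embryo uniqueness.
boundary_fixture <- function() {
  sp <- spec7()
  tb <- table7()
  diverse7 <- tb$key[tb$size == 7L & tb$complexity == 6L]   # diversity 6979
  P <- diverse7[1]; B8 <- diverse7[2]; B11 <- diverse7[3]; B9 <- diverse7[4]
  pst <- parse_key(P, sp)
  ev <- valid_events(pst, sp)
  exc <- ev[ev$kind == "excision" & ev$site_b - ev$site_a == 4L, ]
  C1 <- canonical_key(apply_event(pst, exc$site_a[1], exc$site_b[1], "excision", sp))
  C2 <- canonical_key(apply_event(pst, exc$site_a[2], exc$site_b[2], "excision", sp))
  stopifnot(C1 != C2, barcode_size(c(C1, C2)) == c(3, 3))
  B10 <- tb$key[tb$size == 3L & tb$complexity == 4L][1]     # diversity 133
  B12 <- canonical_key(-(7:1))                              # complexity 1, diversity 9
  stopifnot(!(B10 %in% c(C1, C2)))
  counts <- tibble::tibble(
    sample_id = c(rep("E01_EryP", 3),
                  rep("E02_EryP", 5),
                  "E03_EryP",
                  "E04_EryP", "E04_EryP",
                  "E05_EryP", "E05_EryP"),
    key = c(P, C1, C2,
            canonical_key(1:7), "+3", "+1+1", "B7KEY", B8,
            B9,
            B9, B10,
            B11, B12),
    reads = c(1500L, 149L, 150L,
              500L, 500L, 500L, 99L, 100L,
              300L,
              300L, 400L,
              2000L, 800L)
  )
  counts$key[counts$key == "B7KEY"] <- diverse7[5]
  list(sp = sp, tb = tb, counts = counts,
       samples = flat_sheet(sprintf("E%02d", 1:5)),
       P = P, C1 = C1, C2 = C2, B7 = diverse7[5], B8 = B8, B9 = B9,
       B10 = B10, B11 = B11, B12 = B12)
}
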