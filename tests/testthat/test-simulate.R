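test_that("cohort simulation is deterministic given a seed", {
  cfg <- noise_free_config(n_embryos = 2L, n_precursors = 10L)
  tab <- table7()
  a <- simulate_cohort(cfg, seed = 5, table = tab)
  b <- simulate_cohort(cfg, seed = 5, table = tab)
  expect_identical(a$truth, b$truth)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_cohort(cfg, seed = 6, table = tab)
  expect_false(identical(a$counts, c2$counts))
})

test_that("noise-free counts carry exactly the truth key set", {
  cfg <- noise_free_config(n_embryos = 2L, n_precursors = 15L)
  coh <- simulate_cohort(cfg, seed = 11, table = table7())
  expect_setequal(unique(coh$counts$key), unique(coh$truth$key))
  expect_equal(nrow(coh$artifacts), 0L)
  # reads conservation
  expect_equal(sum(coh$counts$reads), sum(coh$truth_cells$reads))
})

test_that("without Cre exposure every cell keeps the unrecombined reference", {
  cfg <- cohort_config(lambda = 0, n_embryos = 1L, n_precursors = 5L,
                       ensure_informative = FALSE, chimera_rate = 0,
                       error_barcode_rate = 0, pcr_noise_sd = 0)
  coh <- simulate_cohort(cfg, seed = 3, table = table7())
  expect_setequal(coh$truth$key, canonical_key(1:7))
  # and the structure filter later removes all of it
  expect_equal(nrow(remove_malformed(coh$counts, cfg$spec)), 0L)
})

test_that("chimeras are signed-element subsets of their parents with sub-threshold fractions", {
  cfg <- cohort_config(n_embryos = 2L, n_precursors = 40L, chimera_rate = 0.3,
                       error_barcode_rate = 0)
  coh <- simulate_cohort(cfg, seed = 21, table = table7())
  chim <- coh$artifacts[coh$artifacts$type == "chimera", ]
  expect_gt(nrow(chim), 0L)
  for (i in seq_len(nrow(chim))) {
    child <- parse_key(chim$key[i], cfg$spec)
    parent <- parse_key(chim$parent_key[i], cfg$spec)
    expect_true(all(child %in% parent))
    expect_lt(length(child), length(parent))
  }
  # reads conservation with artifacts included
  expect_equal(sum(coh$counts$reads),
               sum(coh$truth_cells$reads) + sum(coh$artifacts$reads))
})

test_that("error barcodes stay below the detection threshold and are filtered", {
  cfg <- cohort_config(n_embryos = 2L, n_precursors = 40L, chimera_rate = 0,
                       error_barcode_rate = 0.2)
  coh <- simulate_cohort(cfg, seed = 8, table = table7())
  err <- coh$artifacts[coh$artifacts$type == "error", ]
  expect_gt(nrow(err), 0L)
  expect_true(all(err$reads < 100))
  res <- evaluate_recovery(coh)
  expect_false(any(err$key %in% res$informative$key))
})

test_that("noise-free recovery of the informative set, labels and biomass is exact", {
  cfg <- noise_free_config()
  coh <- simulate_cohort(cfg, seed = 17, table = table7())
  res <- evaluate_recovery(coh)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$label_accuracy, 1)
  expect_equal(res$biomass_max_abs_err, 0, tolerance = 1e-9)
})

test_that("the pipeline writes a reproducible artifact set", {
  cfg <- noise_free_config(n_embryos = 2L, n_precursors = 12L)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  coh <- simulate_cohort(cfg, seed = 4, table = table7())
  run_pipeline(cohort = coh, out_dir = d1)
  run_pipeline(cohort = coh, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  tab <- read_tsv_meta(file.path(d1, "informative_barcodes.tsv"))
  expect_true(all(c("key", "embryo_id", "cell_equiv") %in% names(tab)))
})

test_that("barcode tables round trip through TSV", {
  tb <- table7()
  p <- tempfile(fileext = ".tsv")
  write_barcode_table(tb, p)
  back <- read_barcode_table(p)
  expect_setequal(back$key, tb$key)
  expect_equal(back$closed, tb$closed)
  expect_equal(lookup_complexity(back, tb$key[100]), tb$complexity[100])
  expect_equal(
    dplyr::arrange(back$class_index, size, complexity)$diversity,
    dplyr::arrange(tb$class_index, size, complexity)$diversity
  )
})
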