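test_that("each filter rule removes exactly its boundary cases", {
  fx <- boundary_fixture()
  res <- filter_barcodes(fx$counts, fx$samples, fx$tb, filter_config(), fx$sp)
  informative <- res$informative
  expect_setequal(informative$key, c(fx$P, fx$B8, fx$B11))
  expect_setequal(informative$embryo_id[informative$key == fx$P], "E01")
  audit <- res$audit
  stage_of <- stats::setNames(audit$stage, paste(audit$key, audit$sample_id))
  expect_equal(unname(stage_of[paste(canonical_key(1:7), "E02_EryP")]), "structure")
  expect_equal(unname(stage_of[paste("+3", "E02_EryP")]), "structure")
  expect_equal(unname(stage_of[paste("+1+1", "E02_EryP")]), "structure")
  expect_equal(unname(stage_of[paste(fx$C1, "E01_EryP")]), "pcr_artifact")
  expect_equal(unname(stage_of[paste(fx$B7, "E02_EryP")]), "read_threshold")
  expect_equal(unname(stage_of[paste(fx$C2, "E01_EryP")]), "clonality")
  expect_equal(unname(stage_of[paste(fx$B9, "E03_EryP")]), "clonality")
  expect_equal(unname(stage_of[paste(fx$B9, "E04_EryP")]), "clonality")
  expect_equal(unname(stage_of[paste(fx$B10, "E04_EryP")]), "clonality")
  expect_equal(unname(stage_of[paste(fx$B12, "E05_EryP")]), "clonality")
})

test_that("the parent filter uses strict inequality and signed-set containment", {
  counts <- tibble::tibble(
    sample_id = "S",
    key = c("+1+2+3+4+5", "+1+2+3", "+3+4+5", "-1-2-3"),
    reads = c(600L, 59L, 60L, 10L)
  )
  out <- pcr_artifact_filter(counts, 0.10)
  expect_false("+1+2+3" %in% out$key)   # 59 < 60
  expect_true("+3+4+5" %in% out$key)    # 60 is not strictly less
  expect_true("-1-2-3" %in% out$key)    # inverted elements: not a subset
  # no superset parent: retained regardless of reads
  lone <- tibble::tibble(sample_id = "S", key = "+6+7", reads = 1L)
  expect_equal(nrow(pcr_artifact_filter(lone, 0.10)), 1L)
})

test_that("read threshold keeps the boundary value and warns when empty", {
  counts <- tibble::tibble(sample_id = "S", key = c("+1", "+2"), reads = c(99L, 100L))
  out <- read_threshold(counts, 100)
  expect_equal(out$key, "+2")
  expect_warning(read_threshold(tibble::tibble(sample_id = "S", key = "+1",
                                               reads = 5L), 100),
                 "below the read threshold")
})

test_that("cell-equivalent normalisation is exact and linear", {
  counts <- tibble::tibble(sample_id = "S1", key = "+1+2+3", reads = 200000L)
  sheet <- tibble::tibble(sample_id = "S1", embryo_id = "E1", population = "EryP",
                          cells_sorted = 50000L, total_reads = 1000000L)
  out <- normalize_reads_per_cell(counts, sheet)
  expect_equal(out$cell_equiv, 10000)
  # equal read fractions, different cell counts: proportional values
  counts2 <- tibble::tibble(sample_id = c("A", "B"), key = "+1+2+3",
                            reads = c(100L, 1000L))
  sheet2 <- tibble::tibble(sample_id = c("A", "B"), embryo_id = "E1",
                           population = "EryP",
                           cells_sorted = c(1000L, 5000L),
                           total_reads = c(1000L, 10000L))
  out2 <- normalize_reads_per_cell(counts2, sheet2)
  expect_equal(out2$cell_equiv, c(100, 500))
  sheet2$cells_sorted[1] <- NA
  expect_error(normalize_reads_per_cell(counts2, sheet2), "A")
})

test_that("class-diversity cut is strictly greater-than", {
  fx <- boundary_fixture()
  m <- normalize_reads_per_cell(
    fx$counts[fx$counts$key == fx$B8, ], fx$samples
  )
  dv <- lookup_class_diversity(fx$tb, fx$B8)
  expect_equal(nrow(clonality_filter(m, fx$tb, min_class_diversity = dv - 1L)), 1L)
  expect_equal(nrow(clonality_filter(m, fx$tb, min_class_diversity = dv)), 0L)
})

test_that("quantifiable subset restricts biomass to 5-9-element barcodes", {
  info <- tibble::tibble(key = c("+1+2+3", "+1+2+3+4+5", "+1+2+3+4+5+6+7",
                                 paste0(rep("+1", 1), "+2+3+4+5+6+7+8+9+10+11+12+13")))
  info$key[4] <- canonical_key(c(1:10, -13, -12, -11))
  out <- quantifiable_subset(info)
  expect_setequal(barcode_size(out$key), c(5, 7))
})

test_that("filters are monotone: tightening never adds barcodes", {
  fx <- boundary_fixture()
  base <- filter_barcodes(fx$counts, fx$samples, fx$tb, filter_config(), fx$sp)
  for (cfg in list(filter_config(min_reads = 500),
                   filter_config(parent_read_fraction = 0.5),
                   filter_config(min_class_diversity = 5000))) {
    tight <- filter_barcodes(fx$counts, fx$samples, fx$tb, cfg, fx$sp)
    expect_true(all(tight$informative$key %in% base$informative$key))
  }
  # and each stage's output is a subset of its input
  s1 <- remove_malformed(fx$counts, fx$sp)
  s2 <- pcr_artifact_filter(s1, 0.1)
  s3 <- read_threshold(s2, 100)
  expect_true(all(paste(s1$key, s1$sample_id) %in% paste(fx$counts$key, fx$counts$sample_id)))
  expect_true(all(paste(s2$key, s2$sample_id) %in% paste(s1$key, s1$sample_id)))
  expect_true(all(paste(s3$key, s3$sample_id) %in% paste(s2$key, s2$sample_id)))
})
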