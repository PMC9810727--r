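make_matrix <- function(rows) {
  # rows: list of c(key, embryo, population, cell_equiv)
  df <- do.call(rbind, lapply(rows, function(r)
    tibble::tibble(key = r[[1]], embryo_id = r[[2]], population = r[[3]],
                   cell_equiv = as.numeric(r[[4]]))))
  tibble::as_tibble(df)
}

test_that("outcome labels follow the blood/endothelium/mesenchyme rule", {
  m <- make_matrix(list(
    list("+1+2+3", "E1", "Endo", 10), list("+1+2+3", "E1", "EryP", 5),
    list("+1+2-4", "E1", "Mes", 10),  list("+1+2-4", "E1", "HPC", 2),
    list("-1+2+3", "E1", "Mes", 1),   list("-1+2+3", "E1", "Endo", 1),
    list("-1+2+3", "E1", "EryP", 1),
    list("+5+6+7", "E1", "Endo", 3),  list("+5+6+7", "E1", "Mes", 3),
    list("+1-5+7", "E1", "Mac", 8),
    list("+2+3+4", "E1", "EryP", 4),  list("+2+3+4", "E1", "Mk", 4)
  ))
  rec <- presence_and_label(m)
  lab <- stats::setNames(rec$label, rec$key)
  expect_equal(unname(lab["+1+2+3"]), "HG")   # blood + endothelium
  expect_equal(unname(lab["+1+2-4"]), "HM")   # blood + mesenchyme
  expect_equal(unname(lab["-1+2+3"]), "MM")   # all three meta-lineages
  expect_equal(unname(lab["+5+6+7"]), "MA")   # endothelium + mesenchyme
  expect_equal(unname(lab["+1-5+7"]), "uni-Haem")
  expect_equal(unname(lab["+2+3+4"]), "EryP+Haem")  # bipotent blood only
})

test_that("labels are invariant to row order and rescaling", {
  m <- make_matrix(list(
    list("+1+2+3", "E1", "Endo", 10), list("+1+2+3", "E1", "EryP", 5),
    list("+9", "E1", "Mes", 1)
  ))
  m$key[m$key == "+9"] <- "+4+5+6"
  base <- presence_and_label(m)
  shuf <- presence_and_label(m[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(base, key)$label, dplyr::arrange(shuf, key)$label)
  scaled <- m; scaled$cell_equiv <- scaled$cell_equiv * 1e6
  expect_equal(dplyr::arrange(presence_and_label(scaled), key)$label,
               dplyr::arrange(base, key)$label)
  zero <- m; zero$cell_equiv <- 0
  expect_error(presence_and_label(zero), "all-zero")
})

test_that("embryo reproducibility counts distinct embryos per outcome", {
  rows <- list()
  for (e in sprintf("E%d", 1:9))
    rows[[length(rows) + 1L]] <- list(paste0("+", length(rows) + 1, "+2+3"), e, "Endo", 5)
  m <- make_matrix(rows)
  m2 <- m; m2$population <- "EryP"; m2$cell_equiv <- 1
  rec <- presence_and_label(dplyr::bind_rows(m, m2))
  rep_tab <- embryo_reproducibility(rec)
  expect_equal(rep_tab$n_embryos[rep_tab$label == "HG"], 9L)
  expect_equal(rep_tab$pct_embryos[rep_tab$label == "HG"], 100)
  expect_true(all(rep_tab$n_embryos <= 9L))
  expect_equal(nrow(rep_tab[rep_tab$label == "MM", ]), 0L)
})

test_that("biomass percentages are exact and sum to 100 per group", {
  m <- make_matrix(list(
    list("+1+2+3+4+5", "E1", "Endo", 300), list("+1+2+3+4+5", "E1", "EryP", 50),
    list("+2+3+4+5+6", "E1", "Endo", 100), list("+2+3+4+5+6", "E1", "Mes", 10)
  ))
  rec <- presence_and_label(m)
  bio <- biomass(rec)
  endo <- bio[bio$group == "Endo", ]
  expect_equal(endo$pct[endo$label == "HG"], 75)
  expect_equal(endo$pct[endo$label == "MA"], 25)
  sums <- tapply(bio$pct, bio$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single-barcode group: all of it
  mes <- bio[bio$group == "Mes", ]
  expect_equal(mes$pct, 100)
  # duplicating every sample's counts leaves biomass unchanged
  rec2 <- presence_and_label(dplyr::bind_rows(m, m))
  bio2 <- biomass(rec2)
  expect_equal(dplyr::arrange(bio2, group, label)$pct,
               dplyr::arrange(bio, group, label)$pct)
})

test_that("shared fractions report both sides of a population pair", {
  m <- make_matrix(list(
    list("+1+2+3+4+5", "E1", "Mac", 10), list("+1+2+3+4+5", "E1", "Microglia", 40),
    list("+2+3+4+5+6", "E1", "Mac", 30), list("+2+3+4+5+6", "E1", "Microglia", 60),
    list("+3+4+5+6+7", "E1", "Microglia", 100)
  ))
  sf <- shared_fraction(m, "Mac", "Microglia")
  expect_equal(unname(sf["Mac"]), 100)
  expect_equal(unname(sf["Microglia"]), 50)
  disjoint <- shared_fraction(m[c(1, 5), ], "Mac", "Microglia")
  expect_equal(unname(disjoint["Mac"]), 0)
  expect_true(is.na(shared_fraction(m[1:2, ], "Mac", "Endo")["Endo"]))
})

test_that("quantifiable fraction returns read- and barcode-weighted shares", {
  counts <- tibble::tibble(
    key = c("+1+2+3+4+5", "+2+3+4+5+6+7+8", "+1+2+3+4+5+6+7+8+9", "+4"),
    reads = c(300L, 300L, 300L, 100L)
  )
  qf <- quantifiable_fraction(counts)
  expect_equal(unname(qf["pct_reads"]), 90)
  expect_equal(unname(qf["pct_barcodes"]), 75)
  none <- quantifiable_fraction(counts[4, ])
  expect_equal(unname(none), c(0, 0))
  all_q <- quantifiable_fraction(counts[1:3, ])
  expect_equal(unname(all_q), c(100, 100))
})

test_that("replicate concordance covers both conventions", {
  expect_equal(unname(replicate_concordance(c("a", "b"), c("a", "b"))),
               c(100, 100, 100))
  expect_equal(unname(replicate_concordance(c("a"), c("b"))[1]), 0)
  r <- replicate_concordance(c("a", "b", "c"), c("a", "b", "d"))
  expect_equal(unname(r["pct_union"]), 50)
  expect_equal(unname(r["pct_rep1"]), 100 * 2 / 3)
  expect_true(all(is.na(replicate_concordance(character(0), "a"))))
})
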