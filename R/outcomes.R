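#' Lineage grouping scheme
#'
#' Maps sorted populations to lineage groups. The default scheme keeps
#' primitive erythrocytes (EryP) separate from the non-erythroid blood
#' (Haem) group — HPC, megakaryocytes and macrophages — alongside
#' endothelium (Endo) and mesenchyme (Mes).
#'
#' @param map Named character vector `population -> group`.
#' @return A named character vector of class `lineage_scheme`.
#' @export
lineage_scheme <- function(map = c(
  EryP = "EryP", HPC = "Haem", Mk = "Haem", Mac = "Haem",
  Endo = "Endo", Mes = "Mes"
)) {
  stopifnot(is.character(map), !is.null(names(map)))
  structure(map, class = c("lineage_scheme", "character"))
}

# blood = EryP and/or Haem; outcome labels are computed on the three
# meta-lineages blood / endothelium / mesenchyme
outcome_label <- function(blood, endo, mes, groups_present) {
  if (blood && endo && mes) return("MM")
  if (blood && endo) return("HG")
  if (blood && mes) return("HM")
  if (endo && mes) return("MA")
  if (length(groups_present) == 1L) return(paste0("uni-", groups_present))
  # blood only, spanning both EryP and Haem
  paste(sort(groups_present), collapse = "+")
}

#' Clonal outcome labels from lineage presence
#'
#' For each informative barcode (one clone) in each embryo, presence in a
#' lineage group means any population of the group carries cell-
#' equivalents above `presence_min` (default: any non-zero signal).
#' Labels: HG (haemangioblast) = blood + endothelium, no mesenchyme; HM
#' (haematomesoblast) = blood + mesenchyme, no endothelium; MA
#' (mesenchymoangioblast) = endothelium + mesenchyme, no blood; MM
#' (multi-outcome mesoderm) = blood + endothelium + mesenchyme; single
#' groups are labelled `uni-<group>`; blood = EryP and/or Haem.
#'
#' @param matrix Informative-barcode tibble with `key`, `embryo_id`,
#'   `population`, `cell_equiv`.
#' @param scheme A [lineage_scheme()].
#' @param presence_min Minimal fraction of the barcode's total cell-
#'   equivalents a group must carry to count as present (default 0: any
#'   non-zero value).
#' @return Tibble: one row per (key, embryo), group cell-equivalent
#'   columns, presence flags (`in_<group>`), `label`.
#' @export
presence_and_label <- function(matrix, scheme = lineage_scheme(),
                               presence_min = 0) {
  unknown <- setdiff(unique(matrix$population), names(scheme))
  if (length(unknown))
    stop("populations missing from the lineage scheme: ",
         paste(unknown, collapse = ", "))
  matrix$group <- unname(scheme[matrix$population])
  groups <- unique(unname(scheme))
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(matrix, .data$key, .data$embryo_id, .data$group),
      cell_equiv = sum(.data$cell_equiv), .groups = "drop"
    ),
    names_from = "group", values_from = "cell_equiv", values_fill = 0
  )
  for (g in setdiff(groups, names(wide))) wide[[g]] <- 0
  gm <- as.matrix(wide[, groups, drop = FALSE])
  if (any(rowSums(gm) <= 0)) stop("barcode with all-zero lineage vector")
  pres <- if (presence_min > 0) gm > presence_min * rowSums(gm) else gm > 0
  blood_groups <- intersect(c("EryP", "Haem"), groups)
  lab <- vapply(seq_len(nrow(gm)), function(r) {
    gp <- groups[pres[r, ]]
    outcome_label(
      blood = any(gp %in% blood_groups),
      endo = "Endo" %in% gp,
      mes = "Mes" %in% gp,
      groups_present = gp
    )
  }, character(1))
  out <- wide
  for (g in groups) out[[paste0("in_", g)]] <- pres[, g]
  out$label <- lab
  out
}

#' Embryo reproducibility of clonal outcomes
#'
#' For each outcome label, the number (and percentage) of distinct embryos
#' containing at least one barcode with that outcome.
#'
#' @param records Output of [presence_and_label()].
#' @param n_embryos Total embryos in the experiment (default: embryos seen
#'   in `records`).
#' @return Tibble (`label`, `n_embryos`, `pct_embryos`).
#' @export
embryo_reproducibility <- function(records, n_embryos = NULL) {
  if (is.null(n_embryos)) n_embryos <- dplyr::n_distinct(records$embryo_id)
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$label),
    n_embryos = dplyr::n_distinct(.data$embryo_id), .groups = "drop"
  )
  out$pct_embryos <- 100 * out$n_embryos / n_embryos
  out
}

#' Lineage biomass by ancestral outcome
#'
#' For each lineage group, the percentage of its summed cell-equivalents
#' (over quantifiable barcodes) contributed by clones of each outcome
#' label: the share of that lineage descending from ancestors of a given
#' fate. Restrict `records` to quantifiable (5-9-element) barcodes before
#' calling.
#'
#' @param records Output of [presence_and_label()] restricted to the
#'   quantifiable subset.
#' @param scheme A [lineage_scheme()] (defines the group columns).
#' @return Tibble (`group`, `label`, `cell_equiv`, `pct`); groups with no
#'   quantifiable barcodes are absent (NA by omission).
#' @export
biomass <- function(records, scheme = lineage_scheme()) {
  groups <- unique(unname(scheme))
  long <- tidyr::pivot_longer(
    records[, c("key", "embryo_id", "label", intersect(groups, names(records)))],
    cols = dplyr::all_of(intersect(groups, names(records))),
    names_to = "group", values_to = "cell_equiv"
  )
  tot <- dplyr::summarise(
    dplyr::group_by(long, .data$group),
    total = sum(.data$cell_equiv), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$label),
    cell_equiv = sum(.data$cell_equiv), .groups = "drop"
  )
  out <- dplyr::inner_join(out, tot, by = "group")
  out <- dplyr::filter(out, .data$total > 0, .data$cell_equiv > 0)
  out$pct <- 100 * out$cell_equiv / out$total
  dplyr::select(out, -"total")
}

#' Shared clonal ancestry between two populations
#'
#' For populations A and B, the percentage of each population's
#' quantifiable cell-equivalents carried by barcodes detected in both:
#' how much of each population descends from ancestors shared with the
#' other.
#'
#' @param matrix Quantifiable informative-barcode tibble (`key`,
#'   `population`, `cell_equiv`).
#' @param pop_a,pop_b Population labels.
#' @return Named numeric: percentage for each side (NA for an empty
#'   population).
#' @export
shared_fraction <- function(matrix, pop_a, pop_b) {
  a <- dplyr::filter(matrix, .data$population == pop_a)
  b <- dplyr::filter(matrix, .data$population == pop_b)
  shared <- intersect(a$key, b$key)
  pct <- function(x) {
    if (nrow(x) == 0L || sum(x$cell_equiv) == 0) return(NA_real_)
    100 * sum(x$cell_equiv[x$key %in% shared]) / sum(x$cell_equiv)
  }
  c(stats::setNames(pct(a), pop_a), stats::setNames(pct(b), pop_b))
}

#' Fraction of reads and barcodes in quantifiable complex classes
#'
#' The share of an embryo's raw barcode repertoire devoted to quantifiable
#' complex barcodes (default 5-9 elements): both the read-weighted and the
#' barcode-count fraction are returned (the time-course statistic after
#' induction).
#'
#' @param counts Raw counts tibble (`key`, `reads`) for one embryo (or any
#'   grouping of interest).
#' @param sizes Quantifiable element counts (default 5:9).
#' @return Named numeric `c(pct_reads, pct_barcodes)` (0 when empty).
#' @export
quantifiable_fraction <- function(counts, sizes = 5:9) {
  if (nrow(counts) == 0L) return(c(pct_reads = 0, pct_barcodes = 0))
  per_key <- dplyr::summarise(
    dplyr::group_by(counts, .data$key),
    reads = sum(.data$reads), .groups = "drop"
  )
  q <- barcode_size(per_key$key) %in% sizes
  c(pct_reads = 100 * sum(per_key$reads[q]) / sum(per_key$reads),
    pct_barcodes = 100 * sum(q) / nrow(per_key))
}

#' Barcode concordance between technical replicates
#'
#' Percentage of shared barcodes across two libraries from the same
#' lysate, under both the Jaccard (shared / union) and the per-replicate
#' (shared / replicate size) conventions.
#'
#' @param keys1,keys2 Character vectors of detected barcode keys.
#' @return Named numeric: `pct_union`, `pct_rep1`, `pct_rep2` (NA when a
#'   replicate is empty).
#' @export
replicate_concordance <- function(keys1, keys2) {
  keys1 <- unique(keys1); keys2 <- unique(keys2)
  if (length(keys1) == 0L || length(keys2) == 0L)
    return(c(pct_union = NA_real_, pct_rep1 = NA_real_, pct_rep2 = NA_real_))
  shared <- length(intersect(keys1, keys2))
  c(pct_union = 100 * shared / length(union(keys1, keys2)),
    pct_rep1 = 100 * shared / length(keys1),
    pct_rep2 = 100 * shared / length(keys2))
}
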