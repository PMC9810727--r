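#' Score pipeline recovery against synthetic ground truth
#'
#' Runs the full filtering cascade and outcome classification on a
#' simulated cohort and scores the result against the generator's truth:
#' precision and recall of the informative (barcode, embryo) set, outcome
#' label accuracy, per-fate-class frequency estimates with their binomial
#' standard errors against the configured probabilities, per-(lineage,
#' label) biomass absolute errors, and an audit that the PCR parent filter
#' removes every generated chimera.
#'
#' @param cohort A `lox_cohort` from [simulate_cohort()].
#' @param filter_cfg A [filter_config()].
#' @param dataset Optional embryo-to-dataset mapping (see
#'   [clonality_filter()]).
#' @return List of metrics plus the intermediate `informative`, `records`
#'   and `biomass` tables.
#' @export
evaluate_recovery <- function(cohort, filter_cfg = filter_config(),
                              dataset = NULL) {
  stopifnot(inherits(cohort, "lox_cohort"))
  config <- cohort$config
  spec <- config$spec
  scheme <- config$scheme

  filt <- filter_barcodes(cohort$counts, cohort$samples, cohort$table,
                          filter_cfg, spec, dataset)
  informative <- filt$informative
  records <- presence_and_label(informative, scheme)
  quant <- quantifiable_subset(records, filter_cfg$quantifiable_sizes)
  bio <- biomass(quant, scheme)

  # truth side: clones the filters are meant to keep
  truth <- cohort$truth
  eligible <- truth_eligible(cohort, filter_cfg, dataset)

  got <- unique(paste(records$key, records$embryo_id))
  want <- unique(paste(eligible$key, eligible$embryo_id))
  precision <- if (length(got)) mean(got %in% want) else NA_real_
  recall <- if (length(want)) mean(want %in% got) else NA_real_

  joined <- dplyr::inner_join(
    records[, c("key", "embryo_id", "label")],
    truth[, c("key", "embryo_id", "fate")],
    by = c("key", "embryo_id")
  )
  label_accuracy <- if (nrow(joined)) mean(joined$label == joined$fate) else NA_real_

  n <- nrow(records)
  fate_freq <- tibble::tibble(
    label = names(config$fate_probs),
    p_truth = unname(config$fate_probs),
    p_est = vapply(names(config$fate_probs),
                   function(l) mean(records$label == l), numeric(1)),
    n = n
  )
  fate_freq$se <- sqrt(fate_freq$p_truth * (1 - fate_freq$p_truth) / n)
  fate_freq$abs_err <- abs(fate_freq$p_est - fate_freq$p_truth)

  truth_bio <- truth_biomass(cohort, filter_cfg$quantifiable_sizes,
                             eligible)
  bio_cmp <- dplyr::full_join(
    bio[, c("group", "label", "pct")],
    truth_bio[, c("group", "label", "pct")],
    by = c("group", "label"), suffix = c("_est", "_truth")
  )
  bio_cmp$pct_est[is.na(bio_cmp$pct_est)] <- 0
  bio_cmp$pct_truth[is.na(bio_cmp$pct_truth)] <- 0
  bio_cmp$abs_err <- abs(bio_cmp$pct_est - bio_cmp$pct_truth)

  # chimera audit: the parent filter alone must remove every chimera
  chim <- cohort$artifacts[cohort$artifacts$type == "chimera", ]
  surv <- pcr_artifact_filter(cohort$counts, filter_cfg$parent_read_fraction)
  chim_surviving <- nrow(dplyr::inner_join(
    chim[, c("sample_id", "key")], surv[, c("sample_id", "key")],
    by = c("sample_id", "key")
  ))

  list(
    precision = precision, recall = recall, label_accuracy = label_accuracy,
    fate_freq = fate_freq, biomass_cmp = bio_cmp,
    biomass_max_abs_err = if (nrow(bio_cmp)) max(bio_cmp$abs_err) else NA_real_,
    chimeras_generated = nrow(chim), chimeras_surviving_parent_filter = chim_surviving,
    n_informative = nrow(records),
    informative = informative, records = records, biomass = bio,
    audit = filt$audit
  )
}

# clones the cascade should report: recombined, >1 element, diverse class,
# unique to one embryo, and read-detectable in at least one sample
truth_eligible <- function(cohort, filter_cfg, dataset = NULL) {
  truth <- cohort$truth
  spec <- cohort$config$spec
  ref_key <- canonical_key(make_reference(spec))
  dv <- lookup_class_diversity(cohort$table, truth$key)
  ds <- if (is.null(dataset)) rep("all", nrow(truth)) else
    unname(dataset[as.character(truth$embryo_id)])
  emb_per_key <- tapply(truth$embryo_id, paste(ds, truth$key),
                        function(x) length(unique(x)))
  unique_embryo <- unname(emb_per_key[paste(ds, truth$key)]) == 1L
  detectable_keys <- unique(
    cohort$truth_cells$key[
      cohort$truth_cells$reads >= filter_cfg$min_reads
    ]
  )
  keep <- truth$size > 1L & truth$key != ref_key &
    !is.na(dv) & dv > filter_cfg$min_class_diversity &
    unique_embryo & truth$key %in% detectable_keys
  truth[keep, , drop = FALSE]
}

# biomass computed from true descendant cells of eligible quantifiable
# clones
truth_biomass <- function(cohort, quantifiable_sizes, eligible) {
  scheme <- cohort$config$scheme
  tc <- cohort$truth_cells
  tc <- tc[paste(tc$clone_id) %in% paste(eligible$clone_id), ]
  tc <- tc[barcode_size(tc$key) %in% quantifiable_sizes, ]
  tc$group <- unname(scheme[tc$population])
  tc <- dplyr::inner_join(tc, cohort$truth[, c("clone_id", "fate")],
                          by = "clone_id")
  tot <- dplyr::summarise(dplyr::group_by(tc, .data$group),
                          total = sum(.data$cells), .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(tc, .data$group, .data$fate),
                          cells = sum(.data$cells), .groups = "drop")
  out <- dplyr::inner_join(out, tot, by = "group")
  out$pct <- 100 * out$cells / out$total
  names(out)[names(out) == "fate"] <- "label"
  out
}
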