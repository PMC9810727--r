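#' Synthetic-cohort configuration
#'
#' Defines the generative model for ground-truthed cohorts: per embryo, a
#' set of precursor cells each receives `Poisson(lambda)` recombination
#' events (a random legal path through the cassette state space, so
#' low-complexity barcodes recur across embryos), a fate class drawn from
#' `fate_probs`, and log-normal numbers of descendant cells in each
#' population of its fate's lineage groups. Reads per (clone, sample) are
#' `cells * reads_per_cell * size_bias[size]` under multiplicative
#' log-normal PCR noise. Artifacts: PCR chimeras are single-excision
#' products of a sampled parent carrying a small fraction of the parent's
#' reads; error barcodes carry sub-threshold read counts.
#'
#' The default cassette has 7 elements: its full recombination closure is
#' exactly enumerable (so class diversities are exact) while its legality
#' pattern under the 82 bp rule — no event spanning fewer than 3 elements
#' — matches the full 13-element cassette.
#'
#' @param spec A [cassette_spec()]; default 7 elements, 10 bp each.
#' @param n_embryos,n_precursors Cohort dimensions (default 9 embryos of
#'   200 barcoded precursors).
#' @param lambda Mean recombination events per precursor (default 5,
#'   emulating accumulated Cre exposure over the induction window).
#' @param fate_probs Named probabilities over fate classes (must sum to 1);
#'   names from `MM`, `HG`, `HM`, `MA`, `uni-EryP`, `uni-Haem`,
#'   `uni-Endo`, `uni-Mes`.
#' @param scheme A [lineage_scheme()] mapping populations to groups.
#' @param clone_size_meanlog,clone_size_sdlog Log-normal descendant-cell
#'   distribution per (clone, population).
#' @param min_cells Floor on descendant cells per contributed population
#'   (default 20 = detection threshold / (depth x strongest
#'   under-amplification) = 100 / (10 x 0.5); contributions below the
#'   method's detection sensitivity are not modelled).
#' @param reads_per_cell Sequencing depth (default 10 reads per cell).
#' @param pcr_noise_sd SD of log-normal read noise (0 = noise-free).
#' @param chimera_rate Expected chimeras per clone per library.
#' @param chimera_fraction_range Chimera reads as a fraction of the
#'   parent's reads (drawn uniformly; keep the upper end below the 10%
#'   parent-filter threshold, or raise it to violate the filter on
#'   purpose).
#' @param error_barcode_rate Expected error barcodes per clone per
#'   library.
#' @param error_read_range Read-count range of error barcodes (keep below
#'   the 100-read detection threshold).
#' @param size_bias Named multiplicative amplification bias per element
#'   count; default over-represents 1-element and under-represents
#'   full-length barcodes. `NULL` = no bias.
#' @param ensure_informative Resample recombination paths so every true
#'   clone is informative by construction: recombined, size > 1, class
#'   diversity above `min_class_diversity`, unique across the cohort, and
#'   never signed-subset-nested within an embryo (so the parent filter
#'   cannot swallow a true clone).
#' @param min_class_diversity Diversity bound used by
#'   `ensure_informative` (default 2000, matching the clonality filter).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(spec = cassette_spec(n_elements = 7),
                          n_embryos = 9L,
                          n_precursors = 200L,
                          lambda = 5,
                          fate_probs = c(
                            MM = 0.2, HG = 0.1, HM = 0.1, MA = 0.1,
                            `uni-EryP` = 0.125, `uni-Haem` = 0.125,
                            `uni-Endo` = 0.125, `uni-Mes` = 0.125
                          ),
                          scheme = lineage_scheme(),
                          clone_size_meanlog = log(300),
                          clone_size_sdlog = 1,
                          min_cells = 20L,
                          reads_per_cell = 10,
                          pcr_noise_sd = 0.3,
                          chimera_rate = 0.05,
                          chimera_fraction_range = c(0.01, 0.09),
                          error_barcode_rate = 0.02,
                          error_read_range = c(10L, 99L),
                          size_bias = NULL,
                          ensure_informative = TRUE,
                          min_class_diversity = 2000L) {
  stopifnot(abs(sum(fate_probs) - 1) < 1e-8, all(fate_probs >= 0),
            chimera_rate >= 0, error_barcode_rate >= 0, lambda >= 0)
  groups <- unique(unname(scheme))
  need <- unlist(lapply(names(fate_probs)[fate_probs > 0], fate_groups))
  miss <- setdiff(setdiff(need, "blood"), groups)
  if (any(need == "blood") && !any(c("EryP", "Haem") %in% groups))
    miss <- c(miss, "EryP/Haem")
  if (length(miss))
    stop("fate classes need lineage groups absent from the scheme: ",
         paste(unique(miss), collapse = ", "))
  if (is.null(size_bias)) {
    size_bias <- rep(1, spec$n_elements)
    names(size_bias) <- seq_len(spec$n_elements)
    size_bias["1"] <- 2
    size_bias[as.character(spec$n_elements)] <- 0.5
  } else if (length(size_bias) == 1L && is.null(names(size_bias))) {
    size_bias <- stats::setNames(rep(size_bias, spec$n_elements),
                                 seq_len(spec$n_elements))
  }
  structure(
    list(spec = spec, n_embryos = as.integer(n_embryos),
         n_precursors = as.integer(n_precursors), lambda = lambda,
         fate_probs = fate_probs, scheme = scheme,
         clone_size_meanlog = clone_size_meanlog,
         clone_size_sdlog = clone_size_sdlog, min_cells = as.integer(min_cells),
         reads_per_cell = reads_per_cell, pcr_noise_sd = pcr_noise_sd,
         chimera_rate = chimera_rate,
         chimera_fraction_range = chimera_fraction_range,
         error_barcode_rate = error_barcode_rate,
         error_read_range = as.integer(error_read_range),
         size_bias = size_bias, ensure_informative = ensure_informative,
         min_class_diversity = as.integer(min_class_diversity)),
    class = "cohort_config"
  )
}

# lineage groups a fate class contributes to; the blood side of HG/HM/MM
# is drawn at simulation time (EryP, Haem, or both)
fate_groups <- function(fate) {
  switch(fate,
    MM = c("blood", "Endo", "Mes"),
    HG = c("blood", "Endo"),
    HM = c("blood", "Mes"),
    MA = c("Endo", "Mes"),
    `uni-EryP` = "EryP",
    `uni-Haem` = "Haem",
    `uni-Endo` = "Endo",
    `uni-Mes` = "Mes",
    stop("unknown fate class: ", fate)
  )
}

#' Simulate a ground-truthed barcoding cohort
#'
#' Draws clones, their barcodes, fates and descendant cells per
#' population, then per-sample read counts with configurable PCR noise,
#' amplification bias, chimeras and error barcodes. One sample per
#' (embryo, population); `cells_sorted` is the sample's total barcoded
#' cells, `total_reads` its total reads including artifacts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the simulation is fully deterministic given
#'   it.
#' @param table Optional precomputed closed `barcode_table` for
#'   `config$spec` (built on the fly when `ensure_informative` needs
#'   one).
#' @return List of class `lox_cohort`: `truth` (one row per clone:
#'   `clone_id`, `embryo_id`, `key`, `size`, `complexity`, `fate`),
#'   `truth_cells` (clone x population cells), `counts` (`sample_id`,
#'   `key`, `reads`), `samples` (sample sheet), `artifacts` (chimera and
#'   error read records), `table`, `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = 1L, table = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  spec <- config$spec
  if (is.null(table))
    table <- enumerate_reachable(spec, max_depth = Inf)
  if (!table$closed)
    stop("need a closed barcode table for the synthetic cassette")
  ref_key <- canonical_key(make_reference(spec))
  scheme <- config$scheme
  groups <- unique(unname(scheme))
  pops_of <- split(names(scheme), unname(scheme))

  # pool of barcodes in diverse classes, for the ensure_informative
  # fallback draw (conditioning on clonality: random recombination mostly
  # yields low-complexity barcodes that the clonality filter would drop)
  dv_all <- lookup_class_diversity(table, table$key)
  pool <- table$key[table$size > 1L & table$key != ref_key &
                      dv_all > config$min_class_diversity]
  if (config$ensure_informative && length(pool) == 0L)
    stop("no (size, complexity) class of this cassette exceeds min_class_diversity")

  used_keys <- new.env(parent = emptyenv())
  clones <- list()
  cells_rows <- list()
  clone_id <- 0L
  for (e in seq_len(config$n_embryos)) {
    embryo <- sprintf("E%02d", e)
    embryo_sets <- list()
    is_ok <- function(key, st) {
      if (key == ref_key || length(st) <= 1L) return(FALSE)
      dv <- lookup_class_diversity(table, key)
      if (is.na(dv) || dv <= config$min_class_diversity) return(FALSE)
      if (!is.null(used_keys[[key]])) return(FALSE)
      ss <- sort(st)
      !any(vapply(embryo_sets, function(o) {
        (length(o) > length(ss) && all(ss %in% o)) ||
          (length(ss) > length(o) && all(o %in% ss))
      }, logical(1)))
    }
    for (p in seq_len(config$n_precursors)) {
      # draw a barcode; under ensure_informative, resample a few times,
      # then fall back to a uniform draw from the diverse-class pool
      ok <- FALSE
      for (try in seq_len(10L)) {
        st <- sample_recombination_path(spec, stats::rpois(1L, config$lambda))
        key <- canonical_key(st)
        if (!config$ensure_informative || is_ok(key, st)) { ok <- TRUE; break }
      }
      if (!ok) {
        for (try in seq_len(500L)) {
          key <- sample(pool, 1L)
          st <- parse_key(key, spec)
          if (is_ok(key, st)) { ok <- TRUE; break }
        }
      }
      if (!ok)
        stop("could not draw an informative barcode; enlarge the cassette or relax ensure_informative")
      used_keys[[key]] <- TRUE
      embryo_sets[[length(embryo_sets) + 1L]] <- sort(st)
      clone_id <- clone_id + 1L
      fate <- sample(names(config$fate_probs), 1L, prob = config$fate_probs)
      gr <- fate_groups(fate)
      if ("blood" %in% gr) {
        blood <- switch(sample.int(3L, 1L), "EryP", "Haem", c("EryP", "Haem"))
        blood <- intersect(blood, groups)
        if (length(blood) == 0L) blood <- intersect(c("EryP", "Haem"), groups)
        gr <- c(setdiff(gr, "blood"), blood)
      }
      pops <- unlist(pops_of[gr], use.names = FALSE)
      cells <- pmax(config$min_cells,
                    round(stats::rlnorm(length(pops), config$clone_size_meanlog,
                                        config$clone_size_sdlog)))
      clones[[clone_id]] <- tibble::tibble(
        clone_id = clone_id, embryo_id = embryo, key = key,
        size = length(st), fate = fate
      )
      cells_rows[[clone_id]] <- tibble::tibble(
        clone_id = clone_id, embryo_id = embryo, key = key,
        population = pops, cells = cells
      )
    }
  }
  truth <- dplyr::bind_rows(clones)
  truth$complexity <- lookup_complexity(table, truth$key)
  truth_cells <- dplyr::bind_rows(cells_rows)
  truth_cells$sample_id <- paste(truth_cells$embryo_id, truth_cells$population, sep = "_")

  # clone reads per sample
  bias <- config$size_bias[as.character(barcode_size(truth_cells$key))]
  bias[is.na(bias)] <- 1
  noise <- if (config$pcr_noise_sd > 0) {
    stats::rlnorm(nrow(truth_cells), -config$pcr_noise_sd^2 / 2, config$pcr_noise_sd)
  } else 1
  truth_cells$reads <- as.integer(pmax(1, round(
    truth_cells$cells * config$reads_per_cell * bias * noise
  )))

  # artifacts
  artifacts <- list()
  for (sid in unique(truth_cells$sample_id)) {
    lib <- truth_cells[truth_cells$sample_id == sid, ]
    lib_artifact_keys <- character(0)
    n_chim <- stats::rpois(1L, config$chimera_rate * nrow(lib))
    for (k in seq_len(n_chim)) {
      parent <- lib[sample.int(nrow(lib), 1L, prob = lib$reads), ]
      pstate <- parse_key(parent$key, spec)
      ev <- valid_events(pstate, spec)
      ev <- ev[ev$kind == "excision", , drop = FALSE]
      if (nrow(ev) == 0L) next
      pick <- ev[sample.int(nrow(ev), 1L), ]
      child <- apply_event(pstate, pick$site_a, pick$site_b, "excision",
                           check = FALSE)
      ckey <- canonical_key(child)
      if (ckey %in% truth$key) next  # avoid colliding with a real clone
      # distinct template-switch events virtually never coincide; keep one
      # chimera per key per library so its reads stay a small fraction of
      # its parent's
      if (ckey %in% lib_artifact_keys) next
      lib_artifact_keys <- c(lib_artifact_keys, ckey)
      stopifnot(all(sort(child) %in% sort(pstate)))  # signed-subset of parent
      frac <- stats::runif(1L, config$chimera_fraction_range[1],
                           config$chimera_fraction_range[2])
      reads <- max(1L, as.integer(round(frac * parent$reads)))
      artifacts[[length(artifacts) + 1L]] <- tibble::tibble(
        type = "chimera", sample_id = sid, key = ckey,
        parent_key = parent$key, reads = reads
      )
    }
    n_err <- stats::rpois(1L, config$error_barcode_rate * nrow(lib))
    for (k in seq_len(n_err)) {
      for (try in 1:50) {
        st <- sample_recombination_path(spec, 1L + stats::rpois(1L, 1))
        ekey <- canonical_key(st)
        if (!(ekey %in% truth$key) && !(ekey %in% lib_artifact_keys)) break
      }
      if (ekey %in% truth$key || ekey %in% lib_artifact_keys) next
      lib_artifact_keys <- c(lib_artifact_keys, ekey)
      artifacts[[length(artifacts) + 1L]] <- tibble::tibble(
        type = "error", sample_id = sid, key = ekey, parent_key = NA_character_,
        reads = sample(seq(config$error_read_range[1],
                           config$error_read_range[2]), 1L)
      )
    }
  }
  artifacts <- if (length(artifacts)) dplyr::bind_rows(artifacts) else
    tibble::tibble(type = character(), sample_id = character(),
                   key = character(), parent_key = character(),
                   reads = integer())

  counts <- dplyr::summarise(
    dplyr::group_by(
      dplyr::bind_rows(
        truth_cells[, c("sample_id", "key", "reads")],
        artifacts[, c("sample_id", "key", "reads")]
      ),
      .data$sample_id, .data$key
    ),
    reads = sum(.data$reads), .groups = "drop"
  )

  # sample sheet: every (embryo, population), dual-indexed
  samples <- tidyr::expand_grid(
    embryo_id = sprintf("E%02d", seq_len(config$n_embryos)),
    population = names(scheme)
  )
  samples$sample_id <- paste(samples$embryo_id, samples$population, sep = "_")
  cs <- tapply(truth_cells$cells, truth_cells$sample_id, sum)
  tr <- tapply(counts$reads, counts$sample_id, sum)
  samples$cells_sorted <- as.integer(ifelse(is.na(cs[samples$sample_id]), 0L,
                                            cs[samples$sample_id]))
  samples$total_reads <- as.integer(ifelse(is.na(tr[samples$sample_id]), 0L,
                                           tr[samples$sample_id]))
  idx <- generate_element_sequences(2L * nrow(samples), length = 8L, min_dist = 3L)
  samples$index1 <- idx[seq_len(nrow(samples))]
  samples$index2 <- idx[nrow(samples) + seq_len(nrow(samples))]
  samples <- samples[, c("sample_id", "embryo_id", "population",
                         "index1", "index2", "cells_sorted", "total_reads")]

  structure(
    list(truth = truth, truth_cells = truth_cells, counts = counts,
         samples = tibble::as_tibble(samples), artifacts = artifacts,
         table = table, config = config, seed = seed),
    class = "lox_cohort"
  )
}

#' @export
print.lox_cohort <- function(x, ...) {
  cat(sprintf(
    "<lox_cohort> %d embryos x %d clones (%d-element cassette), %d count entries, %d artifact reads records (seed %d)\n",
    x$config$n_embryos, x$config$n_precursors, x$config$spec$n_elements,
    nrow(x$counts), nrow(x$artifacts), x$seed
  ))
  invisible(x)
}
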