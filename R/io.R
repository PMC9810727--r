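#' Deterministic TSV writers and readers
#'
#' All pipeline tables are written as plain TSV, sorted on their key
#' columns for diffability, with comment-prefixed header lines recording
#' the package version, the seed and a content hash of the run
#' configuration, so re-runs are byte-identical and auditable.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param sort_by Columns to sort on (default: all character columns, left
#'   to right).
#' @param meta Named character vector written as `# name: value` header
#'   lines.
#' @return `write_tsv_meta()` the path, invisibly; `read_tsv_meta()` a
#'   tibble with the metadata in attribute `meta`.
#' @export
write_tsv_meta <- function(x, path, sort_by = NULL, meta = character(0)) {
  if (is.null(sort_by))
    sort_by <- names(x)[vapply(x, is.character, logical(1))]
  if (length(sort_by))
    x <- x[do.call(order, x[sort_by]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# loxtrace %s",
                     as.character(utils::packageVersion("loxtrace"))), con)
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_meta
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- grep("^#", lines, value = TRUE)
  out <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                             stringsAsFactors = FALSE))
  attr(out, "meta") <- meta
  out
}

#' Serialise a barcode table
#'
#' Writes the barcode-to-complexity map (key, size, complexity) and can
#' rebuild the `barcode_table` object, including the class-diversity
#' index, from such a file.
#'
#' @param table A `barcode_table`.
#' @param path TSV path.
#' @export
write_barcode_table <- function(table, path) {
  write_tsv_meta(
    tibble::tibble(key = table$key, size = table$size,
                   complexity = table$complexity),
    path, sort_by = "key",
    meta = c(
      n_elements = as.character(table$n_elements),
      closed = as.character(table$closed),
      max_depth_built = as.character(table$max_depth_built)
    )
  )
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  x <- read_tsv_meta(path)
  meta <- attr(x, "meta")
  grab <- function(what) sub(paste0("^# ", what, ": "), "",
                             grep(paste0("^# ", what, ":"), meta, value = TRUE))
  class_index <- dplyr::count(x[, c("size", "complexity")],
                              .data$size, .data$complexity, name = "diversity")
  structure(
    list(key = x$key, complexity = x$complexity, size = x$size,
         class_index = class_index,
         closed = as.logical(grab("closed")),
         max_depth_built = as.integer(grab("max_depth_built")),
         n_elements = as.integer(grab("n_elements"))),
    class = "barcode_table"
  )
}

#' Run the full synthetic pipeline and write its artifacts
#'
#' Simulate (or accept) a cohort, run the filtering cascade, classify
#' outcomes and quantify biomass, and write every stage's table under
#' `out_dir`: truth, raw counts, sample sheet, informative barcodes,
#' filter audit, outcome records, embryo reproducibility and biomass.
#' Re-running with the same configuration and seed reproduces the files
#' byte for byte.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param filter_cfg A [filter_config()].
#' @param dataset Optional embryo-to-dataset mapping.
#' @param cohort Optionally, a pre-simulated `lox_cohort` (overrides
#'   `config`/`seed`).
#' @return Invisibly, the [evaluate_recovery()] metrics list.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, out_dir,
                         filter_cfg = filter_config(), dataset = NULL,
                         cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(seed = as.character(cohort$seed),
            cassette = sprintf("%d elements", cohort$config$spec$n_elements))
  res <- evaluate_recovery(cohort, filter_cfg, dataset)
  p <- function(f) file.path(out_dir, f)
  write_tsv_meta(cohort$truth, p("truth_clones.tsv"), meta = meta)
  write_tsv_meta(cohort$counts, p("counts_raw.tsv"), meta = meta)
  write_tsv_meta(cohort$samples, p("sample_sheet.tsv"), meta = meta)
  write_tsv_meta(res$informative, p("informative_barcodes.tsv"), meta = meta)
  write_tsv_meta(res$audit, p("filter_audit.tsv"), meta = meta)
  write_tsv_meta(res$records, p("outcome_records.tsv"), meta = meta)
  write_tsv_meta(embryo_reproducibility(res$records),
                 p("embryo_reproducibility.tsv"), meta = meta)
  write_tsv_meta(res$biomass, p("biomass.tsv"), meta = meta)
  invisible(res)
}
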