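# Plain-text I/O: manifest CSV, islands BED4, signal TSV + sample sheet,
# truth TSV. readr handles gzip transparently in both directions.

#' Read and write the probe manifest CSV
#'
#' Columns: `probe_id`, `chr`, `pos` (1-based), `strand`, `gene`, `region`
#' (both `;`-collapsed, empty for intergenic probes), `cgi_context`.
#'
#' @param probes Annotated probe tibble (see [annotate_manifest()]).
#' @param path File path (`.gz` accepted).
#' @return `read_manifest_csv()` returns the probe tibble;
#'   `write_manifest_csv()` returns `path` invisibly.
#' @export
write_manifest_csv <- function(probes, path) {
  assert_columns(
    probes, c("probe_id", "chr", "pos", "strand", "gene", "region", "cgi_context"),
    "`probes`"
  )
  readr::write_csv(
    probes[, c("probe_id", "chr", "pos", "strand", "gene", "region", "cgi_context")],
    path
  )
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      probe_id = "c", chr = "c", pos = "i", strand = "c",
      gene = "c", region = "c", cgi_context = "c"
    )
  ) |>
    mutate(
      gene = dplyr::coalesce(.data$gene, ""),
      region = dplyr::coalesce(.data$region, "")
    )
}

#' Read and write CpG islands as BED4
#'
#' 0-based half-open intervals, tab-separated, no header.
#'
#' @param islands Tibble with `chr`, `start`, `end`, `name`.
#' @param path File path (`.gz` accepted).
#' @export
write_islands_bed <- function(islands, path) {
  assert_columns(islands, c("chr", "start", "end"), "`islands`")
  if (!"name" %in% names(islands)) islands$name <- "."
  readr::write_tsv(
    islands[, c("chr", "start", "end", "name")], path,
    col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_islands_bed
#' @export
read_islands_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chr", "start", "end", "name"),
    col_types = "ciic"
  )
}

#' Read and write two-channel signals with a sample sheet
#'
#' Signals are stored as a long TSV (`probe_id`, `sample_id`, `A`, `B`);
#' the sidecar sample sheet is a CSV with `sample_id`, `group`.
#'
#' @param signals A `methyl_signals` object or long signal tibble plus a
#'   `samples` tibble.
#' @param path Signal TSV path; the sample sheet is written next to it as
#'   `<path>.samples.csv`.
#' @param samples Sample sheet tibble (when `signals` is a bare tibble).
#' @export
write_signals <- function(signals, path, samples = NULL) {
  if (inherits(signals, "methyl_signals")) {
    samples <- signals$samples
    signals <- signals$signals
  }
  assert_columns(signals, c("probe_id", "sample_id", "A", "B"), "`signals`")
  readr::write_tsv(signals[, c("probe_id", "sample_id", "A", "B")], path)
  if (!is.null(samples)) {
    readr::write_csv(samples, paste0(path, ".samples.csv"))
  }
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  signals <- readr::read_tsv(
    path,
    col_types = readr::cols(probe_id = "c", sample_id = "c", A = "d", B = "d")
  )
  sheet <- paste0(path, ".samples.csv")
  samples <- NULL
  if (file.exists(sheet)) {
    samples <- readr::read_csv(sheet, col_types = readr::cols(.default = "c"))
    signals <- left_join(signals, samples, by = "sample_id") |>
      relocate("probe_id", "sample_id", "group")
  }
  structure(
    list(signals = signals, samples = samples, truth = NULL),
    class = "methyl_signals"
  )
}

#' Write a DMP table as TSV and BED9
#'
#' The BED9 export (0-based half-open single-base intervals, name =
#' probe_id, score = `-10 log10(p_raw)` capped at 1000, colour by call
#' direction) suits genome-browser tracks.
#'
#' @param dmps DMP table with coordinates (called with a manifest).
#' @param path Output TSV path.
#' @param bed_path Optional BED9 output path.
#' @export
write_dmps <- function(dmps, path, bed_path = NULL) {
  readr::write_tsv(as_tibble(dmps), path)
  if (!is.null(bed_path)) {
    assert_columns(dmps, c("chr", "pos"), "`dmps` (BED export)")
    bed <- onebased_to_bed(dmps$pos, dmps$pos)
    colour <- dplyr::case_when(
      dmps$direction == "hyper" ~ "255,0,0",
      dmps$direction == "hypo" ~ "0,128,0",
      .default = "128,128,128"
    )
    readr::write_tsv(
      tibble(
        chr = dmps$chr, start = bed$start, end = bed$end,
        name = dmps$probe_id,
        score = pmin(round(-10 * log10(pmax(dmps$p_raw, 1e-100))), 1000),
        strand = ".", thickStart = bed$start, thickEnd = bed$end,
        itemRgb = colour
      ),
      bed_path,
      col_names = FALSE
    )
  }
  invisible(path)
}

#' Read and write the simulation ground-truth table
#'
#' @param truth Tibble `probe_id`, `is_dmp`, `direction`,
#'   `true_delta_beta`.
#' @param path TSV path (`.gz` accepted).
#' @export
write_truth_tsv <- function(truth, path) {
  assert_columns(truth, c("probe_id", "is_dmp", "direction", "true_delta_beta"), "`truth`")
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = "c", is_dmp = "l", direction = "c", true_delta_beta = "d"
    )
  )
}

#' Bundled reference summary tables
#'
#' Small plain-text tables of published summary statistics from a
#' whole-blood DNA-methylation study of clopidogrel resistance, used in
#' examples and tests: per-chromosome counts of called positions
#' (`"chromosome_counts"`), pathway enrichment rows
#' (`"pathway_enrichment"`), pyrosequencing and qRT-PCR group summaries
#' (`"pyro_summary"`, `"qpcr_summary"`), validation-cohort 2x2 counts
#' (`"cohort_categorical"`), and logistic-regression coefficients
#' (`"logistic_coefficients"`).
#'
#' @param name Table name as above.
#' @return A tibble.
#' @export
methcall_example <- function(name = c(
                               "chromosome_counts", "pathway_enrichment",
                               "pyro_summary", "qpcr_summary",
                               "cohort_categorical", "logistic_coefficients"
                             )) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("cr_", name, ".tsv"),
    package = "methcall", mustWork = TRUE
  )
  readr::read_tsv(path, col_types = readr::cols(), show_col_types = FALSE)
}
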