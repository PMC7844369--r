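# End-to-end orchestration: simulate -> preprocess -> call -> summarize ->
# enrich, with per-stage TSV artifacts and chained JSON stage manifests.

#' Assemble (or load) a pipeline configuration
#'
#' A nested list of stage options; `path` may point to a YAML file with the
#' same structure, and `...` overrides are applied on top. Defaults follow
#' the analysis conventions of the package: beta offset 100, no probe
#' scaling, quantile normalization on, log2 M-values, raw p < 0.01 and
#' |delta-beta| >= 0.2 calling.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides, e.g. `synthetic = list(n_probes = 1000)`,
#'   `preprocess = list(background_level = 200)`,
#'   `thresholds = list(delta_cut = 0.2)`, `gene_sets = "sets.gmt"`,
#'   `seed = 1`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    synthetic = list(),
    signals_path = NULL,
    gene_sets = NULL,
    background_genes = NULL,
    preprocess = list(
      offset = 100, background_level = 0, scaling = FALSE,
      normalize = TRUE, logit_base = "log2", epsilon = 1e-6
    ),
    thresholds = list(
      p_mode = "raw", p_cut = 0.01, fdr_cut = 0.05, delta_cut = 0.2
    ),
    ease = FALSE,
    seed = 1L
  )
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  overrides <- list(...)
  if (length(overrides) > 0) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

stage_manifest <- function(dir, stage, params, inputs, outputs, counts) {
  manifest <- list(
    stage = stage,
    params = params,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)),
    counts = counts
  )
  jsonlite::write_json(
    manifest, file.path(dir, paste0(stage, ".manifest.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest
}

pipeline_log <- function(con, ...) {
  line <- sprintf(...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full differential-methylation pipeline
#'
#' Executes, in order: synthetic-data generation (or signal loading),
#' background correction, optional probe scaling, beta computation,
#' quantile normalization, logit transformation, per-probe rank-sum
#' testing with BH adjustment and hyper/hypo calling, chromosome/region
#' summaries, and (when gene sets are configured) over-representation
#' analysis. Every stage writes a TSV artifact plus a JSON stage manifest
#' recording parameters and MD5 hashes of its inputs and outputs, so a
#' rerun with the same configuration is byte-identical and the manifests
#' chain stage to stage.
#'
#' @param config A [pipeline_config()] (or YAML path / plain list accepted
#'   by it).
#' @param out_dir Output directory, created if needed.
#' @return A run report: per-stage counts, artifact paths and the
#'   configuration, invisibly classed `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- pipeline_config(path = config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  pipeline_log(log_con, "pipeline seed: %s", config$seed)

  # stage: simulate (or load)
  if (!is.null(config$signals_path)) {
    if (!file.exists(config$signals_path)) {
      abort(sprintf("Stage 'simulate': signal file %s not found.", config$signals_path),
        class = "methcall_stage_error"
      )
    }
    sim <- read_signals(config$signals_path)
    manifest <- NULL
    truth <- NULL
  } else {
    scfg <- do.call(synth_config, modifyList(
      config$synthetic %||% list(),
      list(seed = config$seed)
    ))
    manifest <- generate_manifest(scfg)
    sim <- simulate_signals(manifest, scfg)
    truth <- sim$truth
  }
  sig_path <- file.path(out_dir, "signals.tsv")
  write_signals(sim, sig_path)
  man_path <- NULL
  if (!is.null(manifest)) {
    man_path <- file.path(out_dir, "manifest.csv")
    write_manifest_csv(manifest$probes, man_path)
    write_islands_bed(manifest$islands, file.path(out_dir, "islands.bed"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  }
  n_probes <- length(unique(sim$signals$probe_id))
  stage_manifest(
    out_dir, "simulate",
    params = config$synthetic, inputs = character(0),
    outputs = c(sig_path, man_path),
    counts = list(probes = n_probes, samples = nrow(sim$samples))
  )
  pipeline_log(log_con, "simulate: %d probes, %d samples", n_probes, nrow(sim$samples))

  # stage: preprocess (background -> scaling -> beta -> QN -> logit)
  pp <- config$preprocess
  sig <- background_correct(sim$signals, pp$background_level)
  if (isTRUE(pp$scaling)) sig <- scale_intensities(sig)
  beta <- compute_beta(sig, offset = pp$offset)
  if (isTRUE(pp$normalize)) beta <- quantile_normalize(beta, "beta")
  mvals <- m_transform(beta, epsilon = pp$epsilon, base = pp$logit_base)
  beta_path <- file.path(out_dir, "beta.tsv")
  m_path <- file.path(out_dir, "mvalues.tsv")
  readr::write_tsv(beta, beta_path)
  readr::write_tsv(mvals, m_path)
  stage_manifest(
    out_dir, "preprocess",
    params = pp, inputs = sig_path, outputs = c(beta_path, m_path),
    counts = list(probes = n_probes)
  )
  pipeline_log(log_con, "preprocess: offset %s, normalize %s", pp$offset, pp$normalize)

  # stage: call
  thr <- do.call(calling_thresholds, config$thresholds)
  dmps <- call_dmps(mvals, beta, sim$samples, thr, manifest = manifest)
  dmp_path <- file.path(out_dir, "dmps.tsv")
  write_dmps(dmps, dmp_path, bed_path = file.path(out_dir, "dmps.bed"))
  n_hyper <- sum(dmps$direction == "hyper")
  n_hypo <- sum(dmps$direction == "hypo")
  stage_manifest(
    out_dir, "call",
    params = unclass(thr), inputs = c(beta_path, m_path), outputs = dmp_path,
    counts = list(
      probes_in = nrow(dmps), called = n_hyper + n_hypo,
      hyper = n_hyper, hypo = n_hypo
    )
  )
  pipeline_log(
    log_con, "call: %d probes in, %d called (%d hyper, %d hypo)",
    nrow(dmps), n_hyper + n_hypo, n_hyper, n_hypo
  )

  # stage: summarize
  sum_paths <- character(0)
  if (!is.null(manifest)) {
    chrom <- summarize_by_chromosome(dmps)
    chrom_path <- file.path(out_dir, "chromosome_summary.tsv")
    readr::write_tsv(as_tibble(chrom), chrom_path)
    dist_path <- file.path(out_dir, "region_distribution.tsv")
    if (n_hyper + n_hypo > 0) {
      readr::write_tsv(region_distribution(dmps), dist_path)
    } else {
      readr::write_tsv(
        tibble(
          direction = character(0), class = character(0),
          label = character(0), n = integer(0), pct = numeric(0)
        ),
        dist_path
      )
    }
    sum_paths <- c(chrom_path, dist_path)
    stage_manifest(
      out_dir, "summarize",
      params = list(), inputs = dmp_path, outputs = sum_paths,
      counts = list(chromosomes = nrow(chrom))
    )
  }

  # stage: enrich
  enr_path <- NULL
  if (!is.null(config$gene_sets)) {
    if (!file.exists(config$gene_sets)) {
      abort(
        sprintf("Stage 'enrich': gene-set file %s not found.", config$gene_sets),
        class = "methcall_stage_error"
      )
    }
    collection <- read_gmt(config$gene_sets, background = config$background_genes)
    query <- dmps |>
      filter(.data$direction != "none", .data$gene != "") |>
      dplyr::pull("gene")
    query <- unique(unlist(strsplit(query, ";", fixed = TRUE)))
    enr <- overrepresentation(query, collection, ease = isTRUE(config$ease))
    enr_path <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(as_tibble(enr), enr_path)
    stage_manifest(
      out_dir, "enrich",
      params = list(ease = isTRUE(config$ease)),
      inputs = c(dmp_path, config$gene_sets), outputs = enr_path,
      counts = list(sets = nrow(enr), query = attr(enr, "query_size"))
    )
    pipeline_log(log_con, "enrich: %d sets, query %d genes", nrow(enr), attr(enr, "query_size"))
  }

  report <- list(
    out_dir = out_dir,
    seed = config$seed,
    counts = list(
      probes = n_probes, called = n_hyper + n_hypo,
      hyper = n_hyper, hypo = n_hypo
    ),
    artifacts = c(
      signals = sig_path, manifest = man_path %||% NA_character_,
      dmps = dmp_path, enrichment = enr_path %||% NA_character_
    ),
    config = config
  )
  class(report) <- "pipeline_report"
  invisible(report)
}

#' Export machine-readable summaries from a pipeline run directory
#'
#' Re-reads the run artifacts and writes a per-chromosome summary TSV, a
#' region/CpG-context distribution TSV, and `summary.json` holding the
#' headline numbers: total called positions, hyper and hypo counts, the
#' genome-wide hyper:hypo ratio, and the promoter-restricted
#' (TSS200/TSS1500) ratio. Ratios are `null` in the JSON when their
#' denominator is zero.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return The summary list, invisibly.
#' @export
export_summaries <- function(run_dir) {
  dmp_path <- file.path(run_dir, "dmps.tsv")
  missing <- dmp_path[!file.exists(dmp_path)]
  if (length(missing) > 0) {
    abort(
      sprintf(
        "Run directory %s is incomplete; missing: %s.",
        run_dir, paste(basename(missing), collapse = ", ")
      ),
      class = "methcall_io_error"
    )
  }
  dmps <- readr::read_tsv(dmp_path, show_col_types = FALSE)
  n_hyper <- sum(dmps$direction == "hyper")
  n_hypo <- sum(dmps$direction == "hypo")
  ratio <- if (n_hypo > 0) n_hyper / n_hypo else NULL
  promoter_ratio <- NULL
  if ("region" %in% names(dmps) && n_hypo > 0) {
    promoter_ratio <- tryCatch(
      hyper_hypo_ratio(
        mutate(dmps, region = dplyr::coalesce(.data$region, "")),
        region_filter = c("TSS200", "TSS1500")
      ),
      methcall_undefined_value_error = function(e) NULL
    )
  }
  summary <- list(
    total = n_hyper + n_hypo,
    hyper = n_hyper,
    hypo = n_hypo,
    hyper_hypo_ratio = ratio,
    promoter_hyper_hypo_ratio = promoter_ratio
  )
  jsonlite::write_json(
    summary, file.path(run_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if ("chr" %in% names(dmps)) {
    readr::write_tsv(
      as_tibble(summarize_by_chromosome(dmps)),
      file.path(run_dir, "chromosome_summary.tsv")
    )
  }
  invisible(summary)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> %s\n  probes: %d  called: %d (hyper %d, hypo %d)\n",
    x$out_dir, x$counts$probes, x$counts$called, x$counts$hyper, x$counts$hypo
  ))
  invisible(x)
}
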