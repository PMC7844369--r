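# ggplot2 views of the main result types.

#' Per-sample beta-value distributions
#'
#' Density of beta-values per sample, the standard QC view of array
#' bimodality (most probes near 0 or near 1) and between-sample
#' comparability before/after normalization.
#'
#' @param beta Long tibble `probe_id`, `sample_id`, `beta` (and optionally
#'   `group` for colouring).
#' @return A ggplot.
#' @export
plot_beta_distribution <- function(beta) {
  assert_columns(beta, c("sample_id", "beta"), "`beta`")
  aes_line <- if ("group" %in% names(beta)) {
    aes(x = .data$beta, group = .data$sample_id, colour = .data$group)
  } else {
    aes(x = .data$beta, group = .data$sample_id)
  }
  ggplot(beta, aes_line) +
    geom_density() +
    labs(x = expression(beta), y = "Density") +
    theme_minimal()
}

#' Volcano plot of a DMP table
#'
#' @param object A `dmp_tbl` from [call_dmps()].
#' @param ... Unused.
#' @return A ggplot of delta-beta vs -log10 raw p, coloured by call.
#' @method autoplot dmp_tbl
#' @export
autoplot.dmp_tbl <- function(object, ...) {
  thr <- attr(object, "thresholds")
  gg <- ggplot(object, aes(
    x = .data$delta_beta, y = -log10(.data$p_raw),
    colour = .data$direction
  )) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_colour_manual(values = c(
      hyper = "#d7301f", hypo = "#2b8cbe", none = "grey70"
    )) +
    labs(
      x = expression(Delta * beta ~ "(case - control)"),
      y = expression(-log[10] ~ p), colour = "Call"
    ) +
    theme_minimal()
  if (!is.null(thr)) {
    gg <- gg +
      geom_vline(xintercept = c(-thr$delta_cut, thr$delta_cut), linetype = 2) +
      geom_hline(yintercept = -log10(thr$p_cut), linetype = 2)
  }
  gg
}

#' Chromosome summary bar chart
#'
#' @param object A `methyl_chrom_summary` from [summarize_by_chromosome()].
#' @param ... Unused.
#' @return A grouped bar chart of hyper/hypo counts per chromosome.
#' @method autoplot methyl_chrom_summary
#' @export
autoplot.methyl_chrom_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("chr", "n_hypo", "n_hyper")],
    c("n_hypo", "n_hyper"),
    names_to = "direction", values_to = "n"
  ) |>
    mutate(
      direction = ifelse(.data$direction == "n_hypo", "hypo", "hyper"),
      chr = factor(.data$chr, levels = unique(object$chr))
    )
  ggplot(long, aes(x = .data$chr, y = .data$n, fill = .data$direction)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(hyper = "#d7301f", hypo = "#2b8cbe")) +
    labs(x = "Chromosome", y = "Called positions", fill = NULL) +
    theme_minimal()
}

#' Enrichment dot plot
#'
#' @param object An `enrichment_tbl` from [overrepresentation()].
#' @param top Number of top sets (by p) to show.
#' @param ... Unused.
#' @return A dot plot of fold enrichment, dot size = hits, colour = FDR.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, top = 20, ...) {
  d <- head(as_tibble(object), top) |>
    mutate(name = factor(.data$name, levels = rev(unique(.data$name))))
  ggplot(d, aes(
    x = .data$fold, y = .data$name,
    size = .data$k, colour = .data$fdr
  )) +
    geom_point() +
    scale_colour_gradient(low = "#d7301f", high = "#2b8cbe") +
    labs(x = "Fold enrichment", y = NULL, size = "Hits", colour = "FDR") +
    theme_minimal()
}

#' Region / CpG-context distribution bars
#'
#' @param distribution Output of [region_distribution()].
#' @return A faceted bar chart of percentages per annotation class.
#' @export
plot_region_distribution <- function(distribution) {
  assert_columns(distribution, c("direction", "class", "label", "pct"), "`distribution`")
  ggplot(distribution, aes(x = .data$label, y = .data$pct, fill = .data$direction)) +
    geom_col(position = "dodge") +
    facet_wrap(~class, scales = "free_x") +
    scale_fill_manual(values = c(hyper = "#d7301f", hypo = "#2b8cbe")) +
    labs(x = NULL, y = "% of annotations", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
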