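# Per-probe two-group testing on M-values, BH adjustment, hyper/hypo
# calling, and genome-wide summaries.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test of two independent samples. The p-value is
#' computed by exact enumeration when the combined sample size is at most
#' 12 and there are no ties, and by the normal approximation with midranks,
#' tie-corrected variance and continuity correction otherwise; the mode
#' used is recorded in the result.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A one-row tibble: `statistic` (the Mann-Whitney U of `x`),
#'   `p_value`, `mode` (`"exact"` or `"normal_approx"`).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1 || !is.numeric(x) || !is.numeric(y)) {
    abort("`x` and `y` must be non-empty numeric vectors.",
      class = "methcall_argument_error"
    )
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  # all observations tied: zero-variance normal approximation; no evidence
  if (!is.finite(p)) p <- 1
  tibble(
    statistic = unname(wt$statistic),
    p_value = p,
    mode = if (exact) "exact" else "normal_approx"
  )
}

#' @rdname rank_sum_test
#' @export
mann_whitney <- rank_sum_test

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values, optionally against a test family larger
#' than the supplied vector: with `m_total > length(p)` the supplied
#' p-values are adjusted as the smallest members of a family of `m_total`
#' tests, which supports re-adjusting a printed subset of results.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m_total Family size, at least `length(p)`.
#' @return Adjusted p-values in input order, capped at 1.
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1].", class = "methcall_argument_error")
  }
  assert_scalar_number(m_total, "m_total", min = length(p))
  p.adjust(p, method = "BH", n = m_total)
}

#' Thresholds for calling differentially methylated positions
#'
#' The default rule calls a probe when its raw rank-sum p-value is below
#' `p_cut` and |delta-beta| reaches `delta_cut`. With
#' `p_mode = "adjusted"`, the BH-adjusted p-value must instead fall below
#' both `p_cut` and `fdr_cut` (two cuts on the same BH quantity). Raw is
#' the default because with 6 + 6 samples the smallest attainable exact
#' rank-sum p is 2/924, so a genome-wide BH-adjusted p below 0.01 is
#' arithmetically out of reach at array scale.
#'
#' @param p_mode `"raw"` or `"adjusted"`.
#' @param p_cut,fdr_cut,delta_cut Cuts in (0, 1\].
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(p_mode = c("raw", "adjusted"),
                               p_cut = 0.01, fdr_cut = 0.05, delta_cut = 0.2) {
  p_mode <- match.arg(p_mode)
  for (nm in c("p_cut", "fdr_cut", "delta_cut")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("`%s` must be in (0, 1].", nm),
        class = "methcall_argument_error"
      )
    }
  }
  structure(
    list(p_mode = p_mode, p_cut = p_cut, fdr_cut = fdr_cut, delta_cut = delta_cut),
    class = "calling_thresholds"
  )
}

#' Call differentially methylated positions
#'
#' Tests every probe with the Wilcoxon rank-sum test on M-values (case vs
#' control), BH-adjusts the p-values over all tested probes, computes
#' delta-beta as mean case beta minus mean control beta, and calls a
#' direction: `hyper` when all threshold conditions are met and
#' `delta_beta >= delta_cut`, `hypo` when `delta_beta <= -delta_cut`,
#' otherwise `none`.
#'
#' @param mvals Long tibble `probe_id`, `sample_id`, `m` from
#'   [m_transform()].
#' @param betas Long tibble `probe_id`, `sample_id`, `beta`, congruent with
#'   `mvals`.
#' @param samples Tibble mapping `sample_id` to `group`; exactly two groups
#'   with at least two samples each.
#' @param thresholds A [calling_thresholds()].
#' @param manifest Optional `methyl_manifest` (or annotated probe tibble)
#'   whose `chr`, `pos`, `gene`, `region` and `cgi_context` columns are
#'   joined onto the result.
#' @param case_group Label of the case group in `samples$group`; the other
#'   label is the control group.
#' @return A tibble of class `dmp_tbl`: `probe_id`, `delta_beta`, `p_raw`,
#'   `p_adj`, `direction`, plus annotation columns when a manifest is
#'   given.
#' @export
call_dmps <- function(mvals, betas, samples,
                      thresholds = calling_thresholds(),
                      manifest = NULL, case_group = "case") {
  assert_columns(mvals, c("probe_id", "sample_id", "m"), "`mvals`")
  assert_columns(betas, c("probe_id", "sample_id", "beta"), "`betas`")
  assert_columns(samples, c("sample_id", "group"), "`samples`")
  stopifnot(inherits(thresholds, "calling_thresholds"))
  grp <- table(samples$group)
  if (length(grp) != 2 || any(grp < 2)) {
    abort("`samples` must contain exactly two groups with >= 2 samples each.",
      class = "methcall_argument_error"
    )
  }
  if (!case_group %in% names(grp)) {
    abort(sprintf("Case group '%s' not found in `samples$group`.", case_group),
      class = "methcall_argument_error"
    )
  }

  m_mat <- long_to_matrix(mvals, "m")
  b_mat <- long_to_matrix(betas, "beta")
  if (!setequal(rownames(m_mat), rownames(b_mat)) ||
    !setequal(colnames(m_mat), colnames(b_mat))) {
    abort("`mvals` and `betas` are not congruent.",
      class = "methcall_argument_error"
    )
  }
  b_mat <- b_mat[rownames(m_mat), colnames(m_mat), drop = FALSE]
  case_ids <- samples$sample_id[samples$group == case_group]
  ctrl_ids <- samples$sample_id[samples$group != case_group]
  i_case <- match(case_ids, colnames(m_mat))
  i_ctrl <- match(ctrl_ids, colnames(m_mat))
  if (anyNA(c(i_case, i_ctrl))) {
    abort("`samples` lists sample_ids absent from the matrices.",
      class = "methcall_argument_error"
    )
  }

  p_raw <- rowwise_ranksum_p(m_mat[, i_case, drop = FALSE], m_mat[, i_ctrl, drop = FALSE])
  p_adj <- bh_adjust(p_raw)
  delta_beta <- rowMeans(b_mat[, i_case, drop = FALSE]) -
    rowMeans(b_mat[, i_ctrl, drop = FALSE])

  pass_p <- if (thresholds$p_mode == "raw") {
    p_raw < thresholds$p_cut
  } else {
    p_adj < thresholds$p_cut & p_adj < thresholds$fdr_cut
  }
  direction <- dplyr::case_when(
    pass_p & delta_beta >= thresholds$delta_cut ~ "hyper",
    pass_p & delta_beta <= -thresholds$delta_cut ~ "hypo",
    .default = "none"
  )

  out <- tibble(
    probe_id = rownames(m_mat),
    delta_beta = unname(delta_beta),
    p_raw = p_raw,
    p_adj = p_adj,
    direction = direction
  )
  if (!is.null(manifest)) {
    probes <- if (inherits(manifest, "methyl_manifest")) manifest$probes else manifest
    keep <- intersect(
      c("probe_id", "chr", "pos", "gene", "region", "cgi_context"),
      names(probes)
    )
    out <- left_join(out, probes[, keep, drop = FALSE], by = "probe_id")
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("dmp_tbl", class(out))
  out
}

# Vectorized two-sided rank-sum p per row: exact via the Wilcoxon
# distribution for tie-free rows with small n (mirroring the exact branch
# of rank_sum_test), per-row rank_sum_test otherwise.
rowwise_ranksum_p <- function(x_mat, y_mat) {
  n1 <- ncol(x_mat)
  n2 <- ncol(y_mat)
  all_mat <- cbind(x_mat, y_mat)
  n <- nrow(all_mat)
  p <- numeric(n)
  ranks <- t(apply(all_mat, 1, rank))
  has_ties <- apply(all_mat, 1, function(r) anyDuplicated(r) > 0)
  exact_ok <- (n1 + n2) <= 12 & !has_ties
  if (any(exact_ok)) {
    U <- rowSums(ranks[exact_ok, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
    p_hi <- 2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p_lo <- 2 * pwilcox(U, n1, n2)
    p[exact_ok] <- pmin(1, ifelse(U > n1 * n2 / 2, p_hi, p_lo))
  }
  slow <- which(!exact_ok)
  for (i in slow) {
    p[i] <- rank_sum_test(x_mat[i, ], y_mat[i, ])$p_value
  }
  p
}

#' Tabulate called positions by chromosome
#'
#' @param dmps A DMP table from [call_dmps()] (needs `chr` and `direction`),
#'   or any tibble with those columns.
#' @return A tibble of class `methyl_chrom_summary`, one row per chromosome
#'   in karyotype order, with `n_hypo`, `n_hyper` and `n_total` (their
#'   sum); column totals are attached as the `"totals"` attribute.
#' @export
summarize_by_chromosome <- function(dmps) {
  assert_columns(dmps, c("chr", "direction"), "`dmps`")
  called <- filter(dmps, .data$direction != "none")
  out <- called |>
    group_by(chr = .data$chr) |>
    summarise(
      n_hypo = sum(.data$direction == "hypo"),
      n_hyper = sum(.data$direction == "hyper"),
      .groups = "drop"
    ) |>
    mutate(n_total = .data$n_hypo + .data$n_hyper)
  out <- out[chrom_order(out$chr), , drop = FALSE]
  attr(out, "totals") <- c(
    n_hypo = sum(out$n_hypo), n_hyper = sum(out$n_hyper),
    n_total = sum(out$n_total)
  )
  class(out) <- c("methyl_chrom_summary", class(out))
  out
}

#' Ratio of hyper- to hypomethylated positions
#'
#' Optionally restricted to probes whose region annotations intersect a
#' filter set (e.g. `c("TSS200", "TSS1500")` for promoter probes).
#'
#' @param dmps DMP table with `direction` (and `region` when a filter is
#'   used; `;`-separated multi-annotations are honoured).
#' @param region_filter Optional character vector of region labels.
#' @return The ratio count(hyper) / count(hypo).
#' @export
hyper_hypo_ratio <- function(dmps, region_filter = NULL) {
  assert_columns(dmps, "direction", "`dmps`")
  called <- filter(dmps, .data$direction != "none")
  if (!is.null(region_filter)) {
    assert_columns(called, "region", "`dmps`")
    hit <- purrr::map_lgl(
      strsplit(called$region, ";", fixed = TRUE),
      ~ any(.x %in% region_filter)
    )
    called <- called[hit, , drop = FALSE]
  }
  n_hyper <- sum(called$direction == "hyper")
  n_hypo <- sum(called$direction == "hypo")
  if (n_hypo == 0) {
    abort("No hypomethylated sites after filtering; ratio undefined.",
      class = "methcall_undefined_value_error"
    )
  }
  n_hyper / n_hypo
}

#' Functional-region and CpG-context distribution of called positions
#'
#' For hyper- and hypomethylated positions separately: counts and
#' percentages per gene-region annotation, where a probe contributes once
#' per distinct region annotation (intergenic probes contribute a single
#' `intergenic` annotation) and percentages are over the annotation total;
#' and counts and percentages per CpG-island context, where each probe
#' contributes exactly once.
#'
#' @param dmps DMP table carrying `direction`, `region` and `cgi_context`
#'   (i.e. called with a manifest), or bare calls plus a `manifest`.
#' @param manifest Optional `methyl_manifest` or annotated probe tibble to
#'   join annotations from when `dmps` lacks them.
#' @return A tibble with columns `direction`, `class` (`"region"` or
#'   `"cgi"`), `label`, `n`, `pct`.
#' @export
region_distribution <- function(dmps, manifest = NULL) {
  if (!is.null(manifest) && !all(c("region", "cgi_context") %in% names(dmps))) {
    probes <- if (inherits(manifest, "methyl_manifest")) manifest$probes else manifest
    dmps <- left_join(
      dmps, probes[, c("probe_id", "region", "cgi_context")],
      by = "probe_id"
    )
  }
  assert_columns(dmps, c("probe_id", "direction", "region", "cgi_context"), "`dmps`")
  called <- filter(dmps, .data$direction != "none")
  bad <- called$probe_id[is.na(called$cgi_context) | is.na(called$region)]
  if (length(bad) > 0) {
    abort(sprintf("Probe %s has no annotation.", bad[1]),
      class = "methcall_argument_error"
    )
  }
  region_rows <- called |>
    mutate(region = ifelse(.data$region == "", "intergenic", .data$region)) |>
    tidyr::separate_longer_delim("region", ";") |>
    distinct(.data$probe_id, .data$direction, .data$region) |>
    group_by(.data$direction, label = .data$region) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(pct = 100 * .data$n / sum(.data$n), class = "region") |>
    ungroup()
  cgi_rows <- called |>
    group_by(.data$direction, label = .data$cgi_context) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(pct = 100 * .data$n / sum(.data$n), class = "cgi") |>
    ungroup()
  bind_rows(region_rows, cgi_rows) |>
    select("direction", "class", "label", "n", "pct") |>
    arrange(.data$direction, .data$class, dplyr::desc(.data$n))
}
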