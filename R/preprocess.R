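# Two-channel intensities -> beta-values -> normalized M-values, in the
# processing order: background correction, optional probe scaling, beta
# computation, quantile normalization, logit transformation.

signals_tbl <- function(signals) {
  if (inherits(signals, "methyl_signals")) signals$signals else signals
}

#' Background-correct two-channel intensities
#'
#' Subtracts a constant background `level` from both channels and truncates
#' at zero. With `level = 0` the input is returned unchanged (negative
#' intensities, if present, are deliberately preserved for the
#' `max(., 0)` guard in [compute_beta()]).
#'
#' @param signals Long signal tibble with columns `A` and `B` (or a
#'   `methyl_signals` object, from which the tibble is taken).
#' @param level Non-negative background level.
#' @return The signal tibble with corrected `A` and `B`.
#' @export
background_correct <- function(signals, level) {
  signals <- signals_tbl(signals)
  assert_columns(signals, c("A", "B"), "`signals`")
  assert_scalar_number(level, "level", min = 0)
  if (level == 0) {
    return(signals)
  }
  mutate(signals, A = pmax(.data$A - level, 0), B = pmax(.data$B - level, 0))
}

#' Scale each sample's total intensity to a common target
#'
#' "Probe scaling": multiplies both channels of each sample by a factor
#' bringing its median total intensity (A + B) to `target` (default: the
#' median across samples of the per-sample medians). Off by default in
#' [run_pipeline()].
#'
#' @inheritParams background_correct
#' @param target Target median total intensity; `NULL` for the across-sample
#'   median.
#' @return The signal tibble with scaled `A` and `B`.
#' @export
scale_intensities <- function(signals, target = NULL) {
  signals <- signals_tbl(signals)
  assert_columns(signals, c("sample_id", "A", "B"), "`signals`")
  med <- signals |>
    group_by(.data$sample_id) |>
    summarise(med = median(.data$A + .data$B), .groups = "drop")
  if (any(med$med <= 0)) {
    abort("Non-positive median total intensity; cannot scale.",
      class = "methcall_argument_error"
    )
  }
  target <- target %||% median(med$med)
  signals |>
    left_join(mutate(med, .f = target / med), by = "sample_id") |>
    mutate(A = .data$A * .data$.f, B = .data$B * .data$.f) |>
    select(-"med", -".f")
}

#' Compute beta-values from two-channel intensities
#'
#' The methylation fraction of a probe is
#' `beta = max(B, 0) / (max(A, 0) + max(B, 0) + offset)`, where B is the
#' methylated and A the unmethylated channel and `offset` (default 100) is
#' a stabilizing pseudocount that keeps the denominator positive and bounds
#' beta strictly below 1.
#'
#' @inheritParams background_correct
#' @param offset Non-negative pseudocount added to the denominator.
#' @return A long tibble with `beta` replacing `A`/`B`; the offset is
#'   recorded in the `"offset"` attribute.
#' @examples
#' sig <- tibble::tibble(
#'   probe_id = "cg1", sample_id = "s1",
#'   A = c(-50), B = c(300)
#' )
#' compute_beta(sig)$beta # 300 / 400 = 0.75
#' @export
compute_beta <- function(signals, offset = 100) {
  signals <- signals_tbl(signals)
  assert_columns(signals, c("probe_id", "sample_id", "A", "B"), "`signals`")
  assert_scalar_number(offset, "offset", min = 0)
  a <- pmax(signals$A, 0)
  b <- pmax(signals$B, 0)
  den <- a + b + offset
  if (any(den == 0)) {
    bad <- signals$probe_id[den == 0][1]
    abort(
      sprintf(
        "Undefined beta (A = B = 0 with offset 0) at probe %s.", bad
      ),
      class = "methcall_undefined_value_error"
    )
  }
  out <- signals |>
    mutate(beta = b / den) |>
    select(-"A", -"B")
  attr(out, "offset") <- offset
  out
}

#' Quantile-normalize a value column across samples
#'
#' Forces every sample's empirical distribution onto the common reference
#' distribution (the rank-wise mean of the sorted per-sample vectors),
#' preserving ranks within each sample; ties receive the average of the
#' reference values over the tied span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param data Long tibble with columns `probe_id`, `sample_id` and the
#'   value column.
#' @param value Name of the value column (default `"beta"`).
#' @return `data` with the value column normalized; all other columns kept.
#' @export
quantile_normalize <- function(data, value = "beta") {
  assert_columns(data, c("probe_id", "sample_id", value), "`data`")
  mat <- long_to_matrix(data, value)
  if (ncol(mat) < 2) {
    abort("Quantile normalization needs at least 2 samples.",
      class = "methcall_argument_error"
    )
  }
  if (anyNA(mat)) {
    abort("Missing values are not supported by quantile_normalize().",
      class = "methcall_argument_error"
    )
  }
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  long <- matrix_to_long(norm, value)
  extra <- setdiff(names(data), value)
  out <- data |>
    select(dplyr::all_of(extra)) |>
    left_join(long, by = c("probe_id", "sample_id")) |>
    relocate(dplyr::all_of(names(data)))
  for (at in c("offset", "epsilon", "base")) {
    if (!is.null(attr(data, at))) attr(out, at) <- attr(data, at)
  }
  out
}

#' Logit-transform beta-values to M-values
#'
#' `m = log2(beta' / (1 - beta'))` with `beta' = clip(beta, epsilon,
#' 1 - epsilon)`, the variance-stabilized scale on which per-probe tests
#' are run. The natural-log variant is available via `base`; the base does
#' not affect rank-based tests.
#'
#' @param beta Long tibble with columns `probe_id`, `sample_id`, `beta`.
#' @param epsilon Clipping bound in (0, 0.5), keeping M finite.
#' @param base `"log2"` (the M-value convention, default) or `"natural"`.
#' @return Long tibble with an `m` column replacing `beta`; `epsilon` and
#'   `base` recorded as attributes.
#' @export
m_transform <- function(beta, epsilon = 1e-6, base = c("log2", "natural")) {
  assert_columns(beta, c("probe_id", "sample_id", "beta"), "`beta`")
  base <- match.arg(base)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5) {
    abort("`epsilon` must be in (0, 0.5).", class = "methcall_argument_error")
  }
  b <- pmin(pmax(beta$beta, epsilon), 1 - epsilon)
  m <- log(b / (1 - b), base = if (base == "log2") 2 else exp(1))
  out <- beta |>
    mutate(m = m) |>
    select(-"beta")
  attr(out, "epsilon") <- epsilon
  attr(out, "base") <- base
  out
}

#' Invert the M-value transform
#'
#' @param m Numeric vector of M-values.
#' @param base `"log2"` or `"natural"`, matching [m_transform()].
#' @return Beta-values in (0, 1).
#' @export
m_inverse <- function(m, base = c("log2", "natural")) {
  base <- match.arg(base)
  x <- if (base == "log2") 2^m else exp(m)
  x / (1 + x)
}
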