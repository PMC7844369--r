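# Targeted-validation statistics: two-group tests from summary statistics,
# 2x2 chi-squared, and delta-delta-Ct relative expression.

#' Two-sample t-test from group summary statistics
#'
#' Student's t-test computed from per-group mean, SD and n (as printed in
#' figure captions and cohort tables). The default pools the two group
#' variances with `df = n1 + n2 - 2`; `welch = TRUE` uses the
#' Welch-Satterthwaite statistic and df instead.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`n1 >= 2`,
#'   `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return A one-row tibble: `estimate` (mean1 - mean2), `t`, `df`,
#'   `p_value`.
#' @examples
#' pooled_t_test(10.598, 4.396, 30, 8.063, 5.085, 30) # p ~ 0.043
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  for (nm in c("sd1", "sd2")) assert_scalar_number(get(nm), nm, min = 0)
  for (nm in c("n1", "n2")) assert_scalar_number(get(nm), nm, min = 2)
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0) {
      return(tibble(estimate = 0, t = 0, df = n1 + n2 - 2, p_value = 1))
    }
    abort("Both SDs are zero but the means differ; t is degenerate.",
      class = "methcall_degenerate_input_error"
    )
  }
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- diff / se
  tibble(estimate = diff, t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Without continuity correction:
#' `chi2 = N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, df = 1.
#'
#' @param a,b Group 1 yes/no counts.
#' @param c,d Group 2 yes/no counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi2_2x2(26, 4, 21, 9) # chi2 ~ 2.455
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("Counts must be non-negative with a positive total.",
      class = "methcall_argument_error"
    )
  }
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    abort("A zero margin makes the chi-squared statistic undefined.",
      class = "methcall_undefined_value_error"
    )
  }
  N <- sum(counts)
  stat <- N * (a * d - b * c)^2 / prod(margins)
  tibble(statistic = stat, df = 1, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: `dCt = mean(target Ct replicates) - mean(reference Ct
#' replicates)` (reference = housekeeping gene, e.g. GAPDH, replicates
#' averaged); relative expression `= 2^-(dCt - calibrator)`. The
#' calibrator defaults to the mean dCt of the control group, so control
#' samples average to a relative expression near 1.
#'
#' @param ct_data Long tibble with one row per replicate: `sample_id`,
#'   `group`, `target_ct`, `reference_ct` (positive Ct values).
#' @param calibrator Calibrator dCt; `NULL` for the control-group mean.
#' @param control_group Group label used for the default calibrator.
#' @return A tibble per sample: `sample_id`, `group`, `delta_ct`,
#'   `rel_expr`; the calibrator used is in the `"calibrator"` attribute.
#' @export
relative_expression <- function(ct_data, calibrator = NULL,
                                control_group = "control") {
  assert_columns(
    ct_data, c("sample_id", "group", "target_ct", "reference_ct"),
    "`ct_data`"
  )
  if (nrow(ct_data) == 0) {
    abort("`ct_data` has no replicates.", class = "methcall_argument_error")
  }
  if (any(ct_data$target_ct <= 0 | ct_data$reference_ct <= 0, na.rm = TRUE) ||
    anyNA(ct_data$target_ct) || anyNA(ct_data$reference_ct)) {
    abort("Ct values must be positive and non-missing.",
      class = "methcall_argument_error"
    )
  }
  per_sample <- ct_data |>
    group_by(.data$sample_id, .data$group) |>
    summarise(
      delta_ct = mean(.data$target_ct) - mean(.data$reference_ct),
      .groups = "drop"
    )
  if (is.null(calibrator)) {
    ctrl <- per_sample$delta_ct[per_sample$group == control_group]
    if (length(ctrl) == 0) {
      abort(
        sprintf(
          "No samples in control group '%s' to calibrate against.",
          control_group
        ),
        class = "methcall_argument_error"
      )
    }
    calibrator <- mean(ctrl)
  }
  out <- mutate(per_sample, rel_expr = 2^-(.data$delta_ct - calibrator))
  attr(out, "calibrator") <- calibrator
  out
}
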