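test_that("pooled t reproduces all four pyrosequencing p-values to 3 decimals", {
  pyro <- methcall_example("pyro_summary")
  got <- purrr::pmap_dbl(
    pyro[, c("mean_case", "sd_case", "n_case", "mean_control", "sd_control", "n_control")],
    function(mean_case, sd_case, n_case, mean_control, sd_control, n_control) {
      pooled_t_test(mean_case, sd_case, n_case, mean_control, sd_control, n_control)$p_value
    }
  )
  expect_equal(round(got, 3), pyro$p_printed)
  expect_equal(round(got, 3), c(0.043, 0.023, 0.048, 0.011))
})

test_that("pooled t handles identity, degeneracy and group order", {
  same <- pooled_t_test(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  zero <- pooled_t_test(5, 0, 10, 5, 0, 10)
  expect_equal(zero$p_value, 1)
  expect_error(
    pooled_t_test(5, 0, 10, 6, 0, 10),
    class = "methcall_degenerate_input_error"
  )
  expect_error(pooled_t_test(5, 2, 1, 6, 2, 10), class = "methcall_argument_error")
  a <- pooled_t_test(10.598, 4.396, 30, 8.063, 5.085, 30)
  b <- pooled_t_test(8.063, 5.085, 30, 10.598, 4.396, 30)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  # Welch changes df but keeps the estimate
  w <- pooled_t_test(10.598, 4.396, 30, 8.063, 5.085, 12, welch = TRUE)
  p <- pooled_t_test(10.598, 4.396, 30, 8.063, 5.085, 12)
  expect_lt(w$df, p$df)
  expect_equal(w$estimate, p$estimate)
})

test_that("2x2 chi-squared without continuity matches the printed cohort values", {
  cat_tbl <- methcall_example("cohort_categorical")
  got <- purrr::pmap_dbl(
    cat_tbl[, c("g1_yes", "g1_no", "g2_yes", "g2_no")],
    function(g1_yes, g1_no, g2_yes, g2_no) {
      chi2_2x2(g1_yes, g1_no, g2_yes, g2_no)$statistic
    }
  )
  expect_equal(round(got, 3), cat_tbl$chi2_printed)
  # closed form equals the standard uncorrected Pearson test
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(26, 21, 4, 9), 2), correct = FALSE)$statistic
  )
  expect_equal(chi2_2x2(26, 4, 21, 9)$statistic, unname(ref))
})

test_that("chi-squared invariances and error contract hold", {
  base <- chi2_2x2(26, 4, 21, 9)
  expect_equal(chi2_2x2(21, 9, 26, 4)$statistic, base$statistic) # transpose groups
  expect_equal(chi2_2x2(4, 26, 9, 21)$statistic, base$statistic) # swap yes/no
  flat <- chi2_2x2(7, 7, 7, 7)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi2_2x2(5, 0, 7, 0), class = "methcall_undefined_value_error")
  expect_error(chi2_2x2(-1, 2, 3, 4), class = "methcall_argument_error")
})

test_that("logistic fit links estimates to odds ratios and Wald statistics", {
  # balanced outcome, intercept only -> logit(0.5) = 0
  d0 <- data.frame(y = rep(c(0, 1), 25))
  t0 <- tidy(logistic_fit(y ~ 1, d0))
  expect_equal(t0$estimate, 0, tolerance = 1e-8)
  expect_equal(t0$odds_ratio, 1, tolerance = 1e-8)

  set.seed(41)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(-1 + 0.8 * x))
  fit <- logistic_fit(y ~ x, data.frame(x = x, y = y))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$wald, (td$estimate / td$std_error)^2)
  # coefficient recovery within +-0.2 of truth, and agreeing with a
  # grid-search likelihood oracle on the same data
  expect_lt(abs(td$estimate[2] - 0.8), 0.2)
  grid <- grid_logistic_mle(
    x, y,
    b0_grid = seq(-1.6, -0.4, by = 0.01),
    b1_grid = seq(0.2, 1.4, by = 0.01)
  )
  expect_lt(abs(td$estimate[1] - grid[1]), 0.011)
  expect_lt(abs(td$estimate[2] - grid[2]), 0.011)

  g <- glance(fit)
  expect_equal(g$n, 500L)
  expect_true(g$converged)
})

test_that("logistic estimation bias shrinks with sample size", {
  est_at <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
    tidy(logistic_fit(y ~ x, data.frame(x = x, y = y)))$estimate[2]
  }
  small <- mean(vapply(1:20, function(s) est_at(200, s), numeric(1)))
  large <- mean(vapply(1:20, function(s) est_at(2000, 100 + s), numeric(1)))
  expect_lt(abs(large - 0.8), abs(small - 0.8) + 0.02)
  expect_lt(abs(large - 0.8), 0.05)
})

test_that("separation and constant outcomes are rejected", {
  d_sep <- data.frame(x = c(-(5:1), 1:5), y = rep(c(0, 1), each = 5))
  expect_error(logistic_fit(y ~ x, d_sep), "x",
    class = "methcall_convergence_error"
  )
  d_const <- data.frame(x = rnorm(10), y = rep(1, 10))
  expect_error(logistic_fit(y ~ x, d_const), class = "methcall_argument_error")
})

test_that("reported odds ratios recover a published coefficient table", {
  coefs <- methcall_example("logistic_coefficients")
  expect_equal(exp(coefs$estimate), coefs$odds_ratio, tolerance = 1e-3)
  expect_equal(
    (coefs$estimate / coefs$std_error)^2, coefs$wald,
    tolerance = 0.15 # printed inputs are rounded
  )
})

test_that("delta-delta-Ct relative expression follows the doubling rule", {
  ct <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 3),
    group = rep(c("control", "case", "case"), each = 3),
    target_ct = c(19.1, 19.3, 19.2, 20.1, 20.3, 20.2, 18.1, 18.3, 18.2),
    reference_ct = c(15.1, 15.3, 15.2, 15.1, 15.3, 15.2, 15.1, 15.3, 15.2)
  )
  out <- relative_expression(ct)
  # calibrator = control mean dCt = 4.0
  expect_equal(attr(out, "calibrator"), 4.0)
  expect_equal(out$rel_expr[out$sample_id == "s1"], 1.0) # at calibrator
  expect_equal(out$rel_expr[out$sample_id == "s2"], 0.5) # dCt 5.0
  expect_equal(out$rel_expr[out$sample_id == "s3"], 2.0) # one cycle below
  # explicit calibrator bypasses the control group
  out2 <- relative_expression(ct, calibrator = 5.0)
  expect_equal(out2$rel_expr[out2$sample_id == "s2"], 1.0)
  expect_error(relative_expression(ct[0, ]), class = "methcall_argument_error")
  bad <- dplyr::mutate(ct, target_ct = dplyr::if_else(sample_id == "s1", NA_real_, target_ct))
  expect_error(relative_expression(bad), class = "methcall_argument_error")
})
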