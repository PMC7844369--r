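# Logistic regression with odds ratios for the validation cohort.

#' Fit a logistic regression with odds ratios
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], binomial family, tight convergence
#' tolerance, at most 50 iterations) with a divergence guard: a fit that
#' fails to converge, or whose coefficients run away as happens under
#' perfect separation, is an error naming the offending covariate.
#' Per-coefficient Wald chi-squared statistics and odds ratios
#' `exp(estimate)` are exposed through [tidy()].
#'
#' @param formula Model formula with a binary outcome (0/1, logical, or a
#'   two-level factor).
#' @param data Data frame of per-subject covariates and outcome.
#' @return An object of class `logistic_fit` wrapping the glm fit.
#' @seealso [tidy.logistic_fit()], [glance.logistic_fit()]
#' @export
logistic_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2) {
    abort("Outcome is constant; logistic regression is undefined.",
      class = "methcall_argument_error"
    )
  }
  fit <- suppressWarnings(glm(
    formula,
    data = data, family = binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 50)
  ))
  est <- coef(fit)
  runaway <- names(est)[abs(est) > 15 & names(est) != "(Intercept)"]
  if (!fit$converged || length(runaway) > 0) {
    culprit <- if (length(runaway) > 0) runaway[1] else names(which.max(abs(est)))
    abort(
      sprintf(
        "Logistic fit diverged (likely separation) on covariate '%s'.",
        culprit
      ),
      class = "methcall_convergence_error"
    )
  }
  structure(list(fit = fit, formula = formula), class = "logistic_fit")
}

#' Tidy a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `wald` (the Wald chi-squared `(estimate/SE)^2`),
#'   `p_value` (from chi-squared with 1 df), `odds_ratio`.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  wald <- (est / se)^2
  tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    wald = unname(wald),
    p_value = unname(pchisq(wald, df = 1, lower.tail = FALSE)),
    odds_ratio = unname(exp(est))
  )
}

#' One-row summary of a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble: `n`, `deviance`, `null_deviance`, `aic`, `iter`,
#'   `converged`.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  f <- x$fit
  tibble(
    n = length(f$y),
    deviance = f$deviance,
    null_deviance = f$null.deviance,
    aic = f$aic,
    iter = f$iter,
    converged = f$converged
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>\n")
  print(tidy(x))
  invisible(x)
}
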