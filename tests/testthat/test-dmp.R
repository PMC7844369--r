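test_that("exact rank-sum p-values match exhaustive enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(1:6, 7:12)$p_value, 2 / 924)
  set.seed(4)
  for (n1 in 1:5) {
    for (n2 in seq_len(min(10 - n1, 5))) {
      x <- runif(n1)
      y <- runif(n2)
      got <- rank_sum_test(x, y)
      expect_equal(got$mode, "exact")
      expect_equal(got$p_value, enumerate_ranksum_p(x, y),
        tolerance = 1e-12,
        label = sprintf("exact p at n1=%d n2=%d", n1, n2)
      )
    }
  }
})

test_that("identical samples give p = 1 and large/tied samples use the approximation", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$mode, "normal_approx") # ties force the approximation
  big <- rank_sum_test(rnorm(10), rnorm(10))
  expect_equal(big$mode, "normal_approx")
  expect_error(rank_sum_test(numeric(0), 1:3), class = "methcall_argument_error")
  # mann_whitney is the same test
  expect_identical(mann_whitney(1:3, 4:6), rank_sum_test(1:3, 4:6))
})

test_that("BH adjustment matches the quadratic-time reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(0.2, m_total = 7), 1) # 0.2 * 7 capped at 1
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^2
    m <- length(p) + sample(0:50, 1)
    got <- bh_adjust(p, m_total = m)
    expect_equal(got, bh_reference(p, m), tolerance = 1e-12)
    # monotone nondecreasing in sorted-p order, never above 1
    expect_true(!is.unsorted(got[order(p)]))
    expect_true(all(got <= 1))
    expect_true(all(got >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "methcall_argument_error")
  expect_error(bh_adjust(runif(5), m_total = 3), class = "methcall_argument_error")
})

test_that("family-size adjustment reproduces printed pathway FDRs", {
  p <- c(3.82e-6, 1.40e-4, 1.82e-4, 2.35e-4, 3.77e-4)
  expect_equal(
    round(bh_adjust(p, m_total = 256), 4),
    c(0.0010, 0.0150, 0.0150, 0.0150, 0.0193)
  )
})

make_two_group <- function(case_beta, control_beta) {
  n1 <- ncol(case_beta)
  n2 <- ncol(control_beta)
  samples <- tibble::tibble(
    sample_id = c(paste0("c", 1:n1), paste0("n", 1:n2)),
    group = rep(c("case", "control"), c(n1, n2))
  )
  bmat <- cbind(case_beta, control_beta)
  rownames(bmat) <- paste0("p", seq_len(nrow(bmat)))
  colnames(bmat) <- samples$sample_id
  beta <- tibble::tibble(
    probe_id = rep(rownames(bmat), ncol(bmat)),
    sample_id = rep(colnames(bmat), each = nrow(bmat)),
    beta = as.vector(bmat)
  )
  list(beta = beta, m = m_transform(beta), samples = samples)
}

test_that("call_dmps applies the p and delta-beta rule per direction", {
  set.seed(10)
  base <- matrix(runif(20 * 12, 0.35, 0.45), 20, 12)
  base[1, 1:6] <- base[1, 1:6] + 0.4 # clear hyper probe
  base[2, 1:6] <- base[2, 1:6] - 0.3 # clear hypo probe
  base[3, 1:6] <- base[3, 1:6] + 0.1 # below delta_cut: stays none
  d <- make_two_group(base[, 1:6], base[, 7:12])
  dmps <- call_dmps(d$m, d$beta, d$samples)
  expect_s3_class(dmps, "dmp_tbl")
  expect_equal(dmps$direction[1:3], c("hyper", "hypo", "none"))
  expect_true(all(dmps$direction[-(1:2)] == "none"))
  expect_true(all(dmps$p_adj >= dmps$p_raw - 1e-15))
  # hyper implies positive delta, hypo negative
  expect_true(all(dmps$delta_beta[dmps$direction == "hyper"] > 0))
  expect_true(all(dmps$delta_beta[dmps$direction == "hypo"] < 0))
})

test_that("call_dmps is invariant to sample order and antisymmetric in group labels", {
  set.seed(12)
  base <- matrix(runif(30 * 10, 0.2, 0.8), 30, 10)
  base[1:4, 1:5] <- base[1:4, 1:5] + 0.21
  d <- make_two_group(base[, 1:5], base[, 6:10])
  ref <- call_dmps(d$m, d$beta, d$samples)
  # shuffle sample rows and the long-table row order
  perm <- sample(nrow(d$samples))
  shuffled <- call_dmps(
    d$m[sample(nrow(d$m)), ], d$beta[sample(nrow(d$beta)), ],
    d$samples[perm, ]
  )
  expect_equal(
    shuffled[order(match(shuffled$probe_id, ref$probe_id)), ],
    ref,
    ignore_attr = TRUE
  )
  # swapping which group is the case negates deltas and swaps calls
  swapped <- call_dmps(d$m, d$beta, d$samples, case_group = "control")
  expect_equal(swapped$delta_beta, -ref$delta_beta)
  map <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_equal(swapped$direction, unname(map[ref$direction]))
})

test_that("the vectorized per-probe p-values equal per-row rank_sum_test", {
  set.seed(14)
  for (cols in list(c(6, 6), c(3, 4), c(8, 7))) {
    x <- matrix(rnorm(25 * cols[1]), 25)
    y <- matrix(rnorm(25 * cols[2]), 25)
    y[5, ] <- rep(x[5, 1], cols[2]) # force ties in one row
    got <- methcall:::rowwise_ranksum_p(x, y)
    want <- vapply(
      seq_len(25),
      function(i) rank_sum_test(x[i, ], y[i, ])$p_value, numeric(1)
    )
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("call_dmps validates groups and matrix congruence", {
  d <- make_two_group(matrix(0.5, 4, 2), matrix(0.4, 4, 2))
  bad_samples <- dplyr::mutate(d$samples, group = "case")
  expect_error(call_dmps(d$m, d$beta, bad_samples), class = "methcall_argument_error")
  one_each <- d$samples[c(1, 3), ]
  expect_error(call_dmps(d$m, d$beta, one_each), class = "methcall_argument_error")
  expect_error(
    call_dmps(d$m[d$m$probe_id != "p1", ], d$beta, d$samples),
    class = "methcall_argument_error"
  )
})

test_that("chromosome summary counts tally and order chromosomes", {
  dmps <- tibble::tibble(
    probe_id = paste0("p", 1:7),
    chr = c("2", "1", "1", "10", "2", "2", "1"),
    direction = c("hyper", "hypo", "hypo", "hypo", "none", "hypo", "hyper")
  )
  s <- summarize_by_chromosome(dmps)
  expect_equal(s$chr, c("1", "2", "10"))
  expect_equal(s$n_hypo, c(2L, 1L, 1L))
  expect_equal(s$n_hyper, c(1L, 1L, 0L))
  expect_equal(s$n_total, s$n_hypo + s$n_hyper)
  expect_equal(sum(s$n_total), sum(dmps$direction != "none"))
  expect_equal(
    attr(s, "totals"),
    c(n_hypo = 4L, n_hyper = 2L, n_total = 6L)
  )
  empty <- summarize_by_chromosome(dmps[dmps$direction == "none", ][0, ])
  expect_equal(nrow(empty), 0)
})

test_that("hyper/hypo ratio honours region filters and degenerate input", {
  dmps <- tibble::tibble(
    probe_id = paste0("p", 1:6),
    direction = c("hyper", "hyper", "hypo", "hypo", "hypo", "none"),
    region = c("TSS200", "Body", "TSS1500;Body", "Body", "", "TSS200")
  )
  expect_equal(hyper_hypo_ratio(dmps), 2 / 3)
  expect_equal(hyper_hypo_ratio(dmps, c("TSS200", "TSS1500")), 1 / 1)
  only_hyper <- dmps[dmps$direction == "hyper", ]
  expect_error(hyper_hypo_ratio(only_hyper), class = "methcall_undefined_value_error")
  equal <- tibble::tibble(direction = c("hyper", "hypo"))
  expect_equal(hyper_hypo_ratio(equal), 1)
})

test_that("region distribution counts each annotation once per probe", {
  dmps <- tibble::tibble(
    probe_id = c("a", "b", "c"),
    direction = c("hyper", "hyper", "hypo"),
    region = c("TSS1500;Body", "Body", ""),
    cgi_context = c("island", "open_sea", "open_sea")
  )
  out <- region_distribution(dmps)
  hyper_reg <- out[out$direction == "hyper" & out$class == "region", ]
  # probe a contributes to TSS1500 and Body; denominator is 3 annotations
  expect_equal(sum(hyper_reg$n), 3)
  expect_equal(hyper_reg$n[hyper_reg$label == "Body"], 2)
  expect_equal(hyper_reg$pct[hyper_reg$label == "Body"], 200 / 3)
  hypo_cgi <- out[out$direction == "hypo" & out$class == "cgi", ]
  expect_equal(hypo_cgi$label, "open_sea")
  expect_equal(hypo_cgi$pct, 100)
  # every CGI percentage block sums to 100
  for (dir in c("hyper", "hypo")) {
    expect_equal(sum(out$pct[out$direction == dir & out$class == "cgi"]), 100)
  }
  # missing annotation errors with the probe named
  bad <- dplyr::mutate(dmps, cgi_context = c(NA, "island", "island"))
  expect_error(region_distribution(bad), "a", class = "methcall_argument_error")
})
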