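# Independent brute-force oracles, kept free of the package's code paths.

# Two-sided rank-sum p by exhaustive enumeration of all C(n1+n2, n1)
# assignments of ranks to group 1 (valid without ties).
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(r), n1)
  u <- apply(combos, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(u - mu) >= abs(obs - mu) - 1e-9)
}

# Upper-tail hypergeometric P(X >= k) from binomial coefficients.
enumerate_hyper_tail <- function(k, set_size, N, n) {
  j <- k:min(set_size, n)
  sum(choose(set_size, j) * choose(N - set_size, n - j)) / choose(N, n)
}

# Quadratic-time BH step-up reference: adj_i = min over j with p_j >= p_i
# of p_j * m / rank_j, capped at 1.
bh_reference <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ranks <- seq_len(n)
  adj_sorted <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(ps[i:n] * m / ranks[i:n]))
  }
  adj_sorted[order(o)]
}

# Profile of the logistic log-likelihood on a parameter grid.
grid_logistic_mle <- function(x, y, b0_grid, b1_grid) {
  best <- c(NA, NA)
  best_ll <- -Inf
  for (b0 in b0_grid) {
    for (b1 in b1_grid) {
      eta <- b0 + b1 * x
      ll <- sum(y * eta - log1p(exp(eta)))
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(b0, b1)
      }
    }
  }
  best
}
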