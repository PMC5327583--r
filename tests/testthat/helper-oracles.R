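# Fixture builders and independent oracles used across the suite.

# random frequency vector summing to 1
rand_freqs <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

# random repertoire with distinct ids and positive integer counts
rand_repertoire <- function(n, max_count = 50, sample_id = "r") {
  tcr_repertoire(sprintf("clone%04d", sample.int(10 * n, n)),
                 sample.int(max_count, n, replace = TRUE),
                 sample_id = sample_id)
}

# one-way ANOVA variance-component ICC via aov(), independent of the
# closed-form sums used by icc_oneway()
oracle_icc <- function(z) {
  df <- data.frame(val = as.vector(z),
                   subj = factor(rep(seq_len(nrow(z)), times = ncol(z))))
  a <- stats::anova(stats::aov(val ~ subj, data = df))
  msb <- a["subj", "Mean Sq"]
  msw <- a["Residuals", "Mean Sq"]
  k <- ncol(z)
  (msb - msw) / (msb + (k - 1) * msw)
}

# full-enumeration conditioned NB test (naive per-split loop)
oracle_nb_p <- function(counts, factors, alpha) {
  K <- sum(counts)
  qhat <- (counts[1] / factors[1] + counts[2] / factors[2]) / 2
  mu <- factors * qhat
  pmf <- function(x, m) {
    if (alpha <= 0) stats::dpois(x, m) else stats::dnbinom(x, size = 1 / alpha, mu = m)
  }
  pa <- vapply(0:K, function(a) pmf(a, mu[1]) * pmf(K - a, mu[2]),
               numeric(1))
  sum(pa[pa <= pa[counts[1] + 1] * (1 + 1e-7)]) / sum(pa)
}

# direct evaluation of the Renyi sum, used as the diversity oracle
oracle_renyi <- function(p, a) {
  if (is.infinite(a)) return(-log(max(p)))
  if (a == 1) return(-sum(p * log(p)))
  log(sum(p^a)) / (1 - a)
}
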