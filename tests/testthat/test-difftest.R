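# No-replicate differential abundance machinery.

test_that("size factors follow the median-of-ratios contract", {
  m <- cbind(A = c(10, 20, 8, 40), B = c(10, 20, 8, 40))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # column 2 = 3 x column 1: factor ratio is exactly 3
  m2 <- cbind(A = c(10, 20, 8, 40), B = 3 * c(10, 20, 8, 40))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 3)

  # a (100, 0) row is excluded from estimation (all-positive filter)
  m3 <- rbind(m2, big = c(100, 0))
  expect_equal(size_factors(m3), size_factors(m2))

  expect_error(size_factors(cbind(c(1, 2), c(2, 1))), "min_count")

  # equivariance: scaling one column scales its factor, on matrices
  # where the filter set is unchanged
  set.seed(19)
  for (i in 1:10) {
    m <- matrix(sample(5:100, 20, replace = TRUE), 10, 2)
    sf <- size_factors(m)
    m_scaled <- m
    m_scaled[, 2] <- m[, 2] * 4
    sf2 <- size_factors(m_scaled)
    # factors are defined up to the shared geometric-mean scale, so the
    # equivariance shows in the ratio
    expect_equal(unname(sf2[2] / sf2[1]), 4 * unname(sf[2] / sf[1]),
                 tolerance = 1e-12)
  }
})

test_that("blind dispersion estimation subtracts shot noise", {
  m <- rbind(a = c(10, 40), b = c(30, 30), c = c(0, 0))
  est <- blind_dispersion_estimates(m, c(1, 1))
  expect_equal(nrow(est), 2)  # zero-mean row skipped
  expect_equal(est$dispersion[est$clonotype_id == "a"], 0.68)
  # equal normalized counts: variance below shot noise, floored at 0
  expect_equal(est$dispersion[est$clonotype_id == "b"], 0)
})

test_that("dispersion curve fitting recovers exact generative curves", {
  mu <- c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000)
  est <- data.frame(clonotype_id = as.character(seq_along(mu)), mean = mu,
                    dispersion = 0.1 + 5 / mu)
  co <- fit_dispersion_curve(est)
  expect_equal(unname(co), c(0.1, 5), tolerance = 1e-6)

  # all-zero dispersions give the clipped origin
  est0 <- transform(est, dispersion = 0)
  expect_equal(unname(fit_dispersion_curve(est0)), c(0, 0))

  # negative trends are clipped to zero, never negative
  estn <- transform(est, dispersion = pmax(0.2 - 5 / mu, 0))
  expect_true(all(fit_dispersion_curve(estn) >= 0))

  expect_error(fit_dispersion_curve(est[1:5, ]), ">= 10")
  est_deg <- data.frame(clonotype_id = as.character(1:12),
                        mean = rep(4, 12), dispersion = stats::runif(12))
  expect_error(fit_dispersion_curve(est_deg), "degenerate")
})

test_that("median dispersion model is the coefficient-wise median", {
  set.seed(55)
  base <- matrix(sample(5:80, 30, replace = TRUE), 15, 2)
  rownames(base) <- sprintf("c%02d", 1:15)
  model1 <- median_dispersion_model(base)
  expect_length(model1$provenance, 1)
  expect_equal(unname(model1$provenance[[1]]["a0"]), model1$a0)

  # synthetic three-pair provenance: medians taken element-wise
  fake <- model1
  fake$provenance <- list(c(a0 = 0.1, a1 = 2), c(a0 = 0.2, a1 = 9),
                          c(a0 = 0.9, a1 = 4))
  co <- do.call(rbind, fake$provenance)
  expect_equal(stats::median(co[, "a0"]), 0.2)

  m <- structure(list(a0 = 0.2, a1 = 4, floor = 1e-8,
                      provenance = list()), class = "tcr_dispersion")
  expect_equal(dispersion_at(m, 10), 0.2 + 4 / 10)
  expect_equal(dispersion_at(m, 1e12), 0.2, tolerance = 1e-6)
  # floor applies where the curve underflows
  m0 <- structure(list(a0 = 0, a1 = 0, floor = 1e-8,
                       provenance = list()), class = "tcr_dispersion")
  expect_equal(dispersion_at(m0, 5), 1e-8)
})

test_that("the NB exact test matches enumeration and the binomial limit", {
  # equal counts, equal factors: the observed split has maximal mass
  expect_equal(nb_exact_test(c(7, 7), c(1, 1), 0.1), 1)

  # (0, 30) against the brute-force enumeration oracle
  expect_equal(nb_exact_test(c(0, 30), c(1, 1), 0.1),
               oracle_nb_p(c(0, 30), c(1, 1), 0.1), tolerance = 1e-12)

  # Poisson limit with equal factors reduces to binomial(K, 1/2)
  set.seed(61)
  for (i in 1:25) {
    K <- sample(1:50, 1)
    kA <- sample(0:K, 1)
    p_pkg <- nb_exact_test(c(kA, K - kA), c(1, 1), 0)
    p_bin <- stats::binom.test(kA, K, 0.5)$p.value
    expect_equal(p_pkg, p_bin, tolerance = 1e-9)
  }

  # chunked accumulation equals single-pass enumeration
  expect_equal(nb_exact_test(c(40, 160), c(1, 1.3), 0.05, enum_cap = 16),
               nb_exact_test(c(40, 160), c(1, 1.3), 0.05), tolerance = 1e-12)

  expect_error(nb_exact_test(c(1.5, 2), c(1, 1), 0.1), "integers")
  expect_error(nb_exact_test(c(0, 0), c(1, 1), 0.1), ">= 1")
})

test_that("BH adjustment reproduces hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # monotone when sorted; thresholding reproduces step-up rejections
  set.seed(71)
  p <- sort(stats::runif(40))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= -1e-15))
  q <- 0.2
  m <- length(p)
  step_up <- max(c(0L, which(p <= q * seq_len(m) / m)))
  rejected <- seq_len(m) <= step_up
  expect_equal(adj <= q, rejected)
})

test_that("run_difftest wires the pieces together coherently", {
  set.seed(81)
  spec <- simulation_spec(n_clones = 400, read_depth = 2e4, seed = 91)
  mat <- simulate_null_pair(spec)

  res <- run_difftest(mat)
  expect_s3_class(res, "tcr_difftest")
  expect_equal(nrow(res), sum(rowSums(mat) >= 1))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  # swapping columns flips signs but leaves every p-value unchanged
  res_sw <- run_difftest(mat[, 2:1])
  ord <- match(res$clonotype_id, res_sw$clonotype_id)
  expect_equal(res_sw$p_value[ord], res$p_value, tolerance = 1e-12)
  expect_equal(res_sw$log2fc[ord], -res$log2fc, tolerance = 1e-12)

  # identical columns: nothing can be significant
  ident <- cbind(A = mat[, 1], B = mat[, 1])
  rownames(ident) <- rownames(mat)
  res_id <- run_difftest(ident[rowSums(ident) > 0, ])
  expect_equal(sum(res_id$significant), 0)

  # all_samples scope runs over a 3-column matrix with named pairs
  other <- simulate_null_pair(
    simulation_spec(n_clones = 400, read_depth = 2e4, seed = 92))
  cc <- other[, 1][match(rownames(mat), rownames(other))]
  cc[is.na(cc)] <- 0
  mat3 <- cbind(mat, C = cc)
  res3 <- run_difftest(mat3, pairs = list(c("A", "B"), c("A", "C")),
                       model_scope = "all_samples")
  expect_setequal(unique(res3$pair), c("A vs B", "A vs C"))
  expect_s3_class(attr(res3, "dispersion")[["A vs B"]], "tcr_dispersion")
})

test_that("tissue presence summary flags and tests significant clones", {
  # construct a difftest-like result by hand
  res <- structure(
    data.frame(pair = "A vs B",
               clonotype_id = sprintf("c%02d", 1:10),
               base_mean = 50, log2fc = rep(c(3, -3), 5),
               p_value = c(rep(1e-5, 6), rep(0.9, 4)),
               fdr = c(rep(1e-4, 6), rep(0.9, 4)),
               direction = rep(c("increase", "decrease"), 5),
               significant = c(rep(TRUE, 6), rep(FALSE, 4)),
               stringsAsFactors = FALSE),
    model_scope = "per_pair", fdr_threshold = 0.05,
    class = c("tcr_difftest", "data.frame"))

  # tissue carries the significant clones in its high-count tail
  tissue <- tcr_repertoire(
    c(sprintf("c%02d", 1:5), sprintf("t%02d", 1:40)),
    c(c(900, 800, 1000, 700, 850), rep(2, 40)),
    sample_id = "tissue")
  ts <- tissue_presence_summary(res, tissue)
  expect_equal(ts$n_significant, 6)
  expect_equal(ts$n_present, 5)
  expect_equal(ts$fraction_present, 5 / 6)
  expect_gt(mean(ts$log10_tissue_counts), ts$overall_mean_log10)
  expect_lt(ts$p_value, 0.05)

  # no significant clones: zero fractions, no test
  res0 <- res
  res0$significant <- FALSE
  ts0 <- tissue_presence_summary(res0, tissue)
  expect_equal(ts0$n_significant, 0)
  expect_true(is.na(ts0$p_value))

  # significant clones all absent from tissue
  res_abs <- res
  res_abs$clonotype_id <- sprintf("zz%02d", 1:10)
  ts_abs <- tissue_presence_summary(res_abs, tissue)
  expect_equal(ts_abs$fraction_present, 0)
})
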