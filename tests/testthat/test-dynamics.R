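# Binary similarity, Morisita overlap, relative clonality, ICC and
# fold-change analysis.

ps_fixture <- function(n1, n2, n12, d12) {
  structure(list(universe_size = n1 + n2 - n12 + d12, n1 = n1, n2 = n2,
                 n12 = n12, d12 = d12, pair = c("a", "b")),
            class = "tcr_presence")
}

test_that("Jaccard and the BUB family agree with hand values", {
  expect_equal(jaccard_index(ps_fixture(5, 4, 3, 0)), 0.5)
  # with no joint absences BUB reduces exactly to Jaccard
  expect_identical(bub_index(ps_fixture(5, 4, 3, 0)), 0.5)
  expect_equal(bub_index(ps_fixture(5, 4, 3, 2)),
               (3 + sqrt(6)) / (6 + sqrt(6)))
  expect_equal(bub_index(ps_fixture(5, 4, 3, 2)), 0.644949,
               tolerance = 1e-5)
  # disjoint samples collapse BUB2 to -1
  expect_equal(bub2_index(ps_fixture(3, 4, 0, 5)), -1)

  s <- tcr_repertoire(letters[1:4], rep(2, 4), sample_id = "s")
  ident <- presence_summary(s, s)
  expect_equal(jaccard_index(ident), 1)
  expect_equal(bub_index(ident), 1)

  set.seed(15)
  for (i in 1:40) {
    uni <- lapply(1:3, function(j) rand_repertoire(20, sample_id = paste0("u", j)))
    ps <- presence_summary(uni[[1]], uni[[2]], uni)
    b <- bub_index(ps)
    j <- jaccard_index(ps)
    expect_gte(b, 0); expect_lte(b, 1)
    b2 <- bub2_index(ps)
    expect_gte(b2, -1); expect_lte(b2, 1)
    if (ps$d12 > 0 && ps$n12 > 0) expect_gte(b, j)
    if (ps$d12 == 0) expect_identical(b, j)
  }
})

test_that("Morisita overlap spans its extremes and hand value", {
  s1 <- tcr_repertoire(c("x", "y", "z"), c(10, 20, 70), sample_id = "s1")
  s1b <- tcr_repertoire(c("x", "y", "z"), c(30, 60, 210), sample_id = "s1b")
  expect_equal(morisita_overlap(s1, s1b), 1)

  d1 <- tcr_repertoire(c("a", "b"), c(5, 5))
  d2 <- tcr_repertoire(c("c", "d"), c(9, 1))
  expect_equal(morisita_overlap(d1, d2), 0)

  m1 <- tcr_repertoire(c("x", "y"), c(10, 10))
  m2 <- tcr_repertoire(c("x", "y"), c(5, 15))
  expect_equal(morisita_overlap(m1, m2), 400 / 450)

  # symmetry and scale invariance on random pairs
  set.seed(23)
  for (i in 1:20) {
    a <- rand_repertoire(25, sample_id = "a")
    b <- rand_repertoire(25, sample_id = "b")
    cd <- morisita_overlap(a, b)
    expect_equal(morisita_overlap(b, a), cd, tolerance = 1e-12)
    expect_gte(cd, 0); expect_lte(cd, 1 + 1e-12)
    scaled <- tcr_repertoire(b$tab$clonotype_id, b$tab$count * 7,
                             sample_id = "b7")
    expect_equal(morisita_overlap(a, scaled), cd, tolerance = 1e-12)
  }
})

test_that("relative clonality is a reciprocal-antisymmetric ratio", {
  a <- tcr_repertoire(letters[1:5], c(40, 10, 5, 3, 2), sample_id = "a")
  b <- tcr_repertoire(letters[1:5], c(12, 11, 10, 9, 8), sample_id = "b")
  expect_equal(relative_clonality(a, a), 1)
  expect_equal(relative_clonality(a, b) * relative_clonality(b, a), 1,
               tolerance = 1e-12)
  expect_equal(relative_clonality(a, b),
               clonality(a) / clonality(b))
  uniform <- tcr_repertoire(letters[1:4], rep(5, 4))
  expect_error(relative_clonality(a, uniform), "clonality 0")
})

test_that("one-way ICC matches the ANOVA oracle and its fixtures", {
  z <- rbind(c(1, 2), c(2, 3), c(3, 4))
  fit <- icc_oneway(z)
  expect_equal(fit$msb, 2)
  expect_equal(fit$msw, 0.5)
  expect_equal(fit$icc, 0.6)
  expect_equal(fit$s2_a / (fit$s2_a + fit$s2_e), fit$icc,
               tolerance = 1e-12)

  # identical columns: perfect concordance
  z2 <- cbind(1:5, 1:5, 1:5)
  expect_equal(icc_oneway(z2)$icc, 1)

  set.seed(41)
  for (i in 1:50) {
    z <- matrix(stats::rnorm(4 * 3), 4, 3)
    expect_equal(icc_oneway(z)$icc, oracle_icc(z), tolerance = 1e-10)
  }

  # independent white-noise columns: ICC near zero at large n
  set.seed(42)
  iccs <- replicate(20, icc_oneway(matrix(stats::rnorm(2000), 1000, 2))$icc)
  expect_lt(abs(mean(iccs)), 3 * stats::sd(iccs) / sqrt(length(iccs)) + 0.01)

  expect_error(icc_oneway(matrix(1, 1, 2)), "at least 2")
})

test_that("log frequency matrix respects scope and imputation", {
  a <- tcr_repertoire(c("x", "y", "z"), c(50, 30, 20), sample_id = "a")
  b <- tcr_repertoire(c("x", "y", "w"), c(10, 40, 50), sample_id = "b")
  zc <- log_frequency_matrix(list(a, b), scope = "common")
  expect_equal(rownames(zc), c("x", "y"))
  expect_equal(zc["x", "a"], log10(0.5))
  zu <- log_frequency_matrix(list(a, b), scope = "union")
  expect_equal(nrow(zu), 4)
  expect_equal(zu["w", "a"], log10(0.5 / a$read_depth))
})

test_that("fold changes honor scope, imputation and binning boundaries", {
  from <- tcr_repertoire(c("p", "q", "r"), c(10, 30, 960), sample_id = "f")
  to <- tcr_repertoire(c("p", "q", "s"), c(40, 30, 930), sample_id = "t")
  fc <- fold_changes(from, to, scope = "overlap")
  expect_equal(sort(fc$clonotype_id), c("p", "q"))
  expect_equal(fc$fc[fc$clonotype_id == "p"], 2)  # 0.01 -> 0.04
  expect_equal(fc$fc[fc$clonotype_id == "q"], 0)

  # union scope imputes half a count for the absent side
  fu <- fold_changes(from, to, scope = "union")
  expect_equal(nrow(fu), 4)
  r_row <- fu[fu$clonotype_id == "r", ]
  expect_equal(r_row$p_to, 0.5 / to$read_depth)

  # imputation arithmetic: absent at baseline depth 1000, then p = 0.002
  f2 <- tcr_repertoire(c("a", "bulk"), c(2, 998), sample_id = "f2")
  t2 <- tcr_repertoire(c("a", "bulk", "new"), c(2, 996, 2),
                       sample_id = "t2")
  fu2 <- fold_changes(f2, t2, scope = "union")
  expect_equal(fu2$fc[fu2$clonotype_id == "new"],
               log2(0.002 / 0.0005))

  # disjoint overlap is an empty, flagged result
  d1 <- tcr_repertoire("only1", 5, sample_id = "d1")
  d2 <- tcr_repertoire("only2", 5, sample_id = "d2")
  fe <- fold_changes(d1, d2, scope = "overlap")
  expect_equal(nrow(fe), 0)
  expect_true(attr(fe, "empty"))

  bins <- bin_fold_changes(c(-3, 0, 3), c = 2)
  expect_equal(unname(bins$counts), c(1, 1, 1))
  # boundary contract: FC = +/- c land in increase/decrease
  b2 <- bin_fold_changes(c(-2, 2), c = 2)
  expect_equal(unname(b2$counts), c(1, 0, 1))
  expect_error(bin_fold_changes(c(0, 1), c = 0), "> 0")

  # bins always partition, and c = 2 vs c = 1 labels differ exactly on
  # the annulus 1 <= |FC| < 2
  grid <- seq(-4, 4, by = 0.05)
  lab <- function(v, cc) {
    ifelse(v <= -cc, "decrease", ifelse(v >= cc, "increase", "unchanged"))
  }
  for (cc in c(0.5, 1, 2, 3)) {
    b <- bin_fold_changes(grid, cc)
    expect_equal(sum(b$counts), length(grid))
    expect_equal(sum(b$fractions), 1, tolerance = 1e-9)
  }
  mism <- lab(grid, 2) != lab(grid, 1)
  expect_equal(mism, abs(grid) >= 1 & abs(grid) < 2)
})

test_that("compartment adjustment rescales the cutoff as specified", {
  a <- tcr_repertoire(c("x", "y"), c(50, 50), sample_id = "a")
  expect_equal(compartment_adjusted_c(a, a, 2), 2)  # identical profiles

  # p_to = (0.01, 0.01), p_from = (0.1, 0.1): ratio of log2 sums is 2
  from <- tcr_repertoire(c("x", "y", "bulk"), c(100, 100, 800),
                         sample_id = "f")
  to <- tcr_repertoire(c("x", "y", "other"), c(10, 10, 980),
                       sample_id = "t")
  expect_equal(compartment_adjusted_c(from, to, 2), 4)

  set.seed(8)
  for (i in 1:20) {
    x <- rand_repertoire(20, sample_id = "x")
    y <- rand_repertoire(20, sample_id = "y")
    if (length(intersect(x$tab$clonotype_id, y$tab$clonotype_id)) == 0) next
    expect_gt(compartment_adjusted_c(x, y, 2), 0)
  }
})

test_that("pairwise dynamics assembles consistent measures", {
  set.seed(77)
  a <- rand_repertoire(40, sample_id = "a")
  b <- rand_repertoire(40, sample_id = "b")
  row <- pairwise_dynamics(a, b)
  ps <- presence_summary(a, b)
  expect_equal(row$jaccard, jaccard_index(ps))
  expect_equal(row$morisita, morisita_overlap(a, b))
  swapped <- pairwise_dynamics(b, a)
  expect_equal(swapped$jaccard, row$jaccard)
  expect_equal(swapped$morisita, row$morisita, tolerance = 1e-12)
  expect_equal(swapped$relative_clonality * row$relative_clonality, 1,
               tolerance = 1e-12)
})
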