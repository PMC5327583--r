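# Per-clonotype differential abundance testing between two samples of one
# subject, without replicates: median-of-ratios size factors estimated on
# clonotypes with >=5 counts in at least one sample, a negative-binomial
# dispersion-mean curve taken as the median over sample pairs, and a
# conditioned two-sided NB exact test per clonotype.

#' Median-of-ratios size factors
#'
#' Estimates one normalization constant per column of a clonotype count
#' matrix. Because repertoire tables are dominated by low-count clones,
#' estimation is restricted to clonotypes with at least \code{min_count}
#' counts in some sample (default 5) and nonzero counts in every sample
#' (so the row geometric mean is defined). The size factor of column
#' \eqn{j} is the median over retained rows of
#' \eqn{f_{ij} / (\prod_j f_{ij})^{1/k}}. Factors are returned unscaled.
#' Rows excluded from estimation are still tested downstream.
#'
#' @param mat integer count matrix (clonotypes x samples), >= 2 columns.
#' @param min_count row filter: maximum count across samples must reach
#'   this value.
#' @return Named numeric vector of positive size factors, one per
#'   column.
#' @export
size_factors <- function(mat, min_count = 5) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_usage("size factors need >= 2 columns")
  keep <- apply(mat, 1, max) >= min_count & apply(mat, 1, min) > 0
  if (!any(keep)) {
    stop_usage(
      "no clonotypes pass the size-factor filter (max count >= %g and present in all samples); try a lower min_count",
      min_count)
  }
  logs <- log(mat[keep, , drop = FALSE])
  log_geo <- rowMeans(logs)
  sf <- exp(apply(logs - log_geo, 2, stats::median))
  names(sf) <- colnames(mat)
  sf
}

#' Blind per-clonotype dispersion estimates from a sample pair
#'
#' Treats the two samples as if they were replicates ("blind"
#' estimation): for clonotype \eqn{i} with normalized counts
#' \eqn{q_{ij} = f_{ij}/s_j}, the method-of-moments raw dispersion is
#' \deqn{\hat\alpha_i = \frac{\mathrm{var}(q_i) - \bar q_i \cdot
#'   \overline{1/s}}{\bar q_i^2}}
#' floored at 0, where the subtracted term removes the expected
#' shot-noise (Poisson) variance. This deliberately absorbs the normal
#' between-time-point variation of the repertoire into the dispersion,
#' compensating for the absence of replicates. Rows with zero mean are
#' skipped.
#'
#' @param mat a 2-column count matrix.
#' @param factors size factors for the two columns (see
#'   \code{\link{size_factors}}).
#' @return Data frame with columns \code{clonotype_id}, \code{mean}
#'   (mean normalized count) and \code{dispersion} (raw
#'   method-of-moments estimate, >= 0).
#' @export
blind_dispersion_estimates <- function(mat, factors) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 2L) stop_usage("dispersion estimation needs 2 columns")
  if (length(factors) != 2L || any(!is.finite(factors)) ||
      any(factors <= 0)) {
    stop_usage("'factors' must be 2 positive size factors")
  }
  q <- sweep(mat, 2, factors, "/")
  qbar <- rowMeans(q)
  keep <- qbar > 0
  q <- q[keep, , drop = FALSE]
  qbar <- qbar[keep]
  v <- (q[, 1] - q[, 2])^2 / 2  # sample variance, n - 1 = 1
  disp <- pmax((v - qbar * mean(1 / factors)) / qbar^2, 0)
  ids <- rownames(mat)[keep]
  if (is.null(ids)) ids <- as.character(which(keep))
  data.frame(clonotype_id = ids, mean = qbar, dispersion = disp,
             stringsAsFactors = FALSE)
}

#' Fit the dispersion-mean curve
#'
#' Least-squares fit of the parametric family
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} to raw per-clonotype dispersion
#' estimates, with both coefficients clipped at 0.
#'
#' @param est the data frame from
#'   \code{\link{blind_dispersion_estimates}} (needs >= 10 clonotypes
#'   with positive mean).
#' @return Named numeric vector \code{c(a0, a1)}, both >= 0.
#' @export
fit_dispersion_curve <- function(est) {
  est <- est[is.finite(est$mean) & est$mean > 0, , drop = FALSE]
  if (nrow(est) < 10L) {
    stop_usage("dispersion fit needs >= 10 clonotypes with positive mean (got %d)",
               nrow(est))
  }
  x <- 1 / est$mean
  if (stats::sd(x) == 0) {
    stop_usage("dispersion fit degenerate: all clonotype means equal")
  }
  co <- stats::coef(stats::lm(est$dispersion ~ x))
  c(a0 = max(unname(co[1]), 0), a1 = max(unname(co[2]), 0))
}

#' Median-of-curves dispersion model
#'
#' Fits one dispersion-mean curve per 2-column sample pair and combines
#' them by the element-wise median of the coefficients, yielding a
#' single \eqn{\alpha(\mu) = a_0 + a_1/\mu} shared by all comparisons.
#' The coefficient-wise median is order-independent and robust to one
#' aberrant pair. The per-pair coefficient vectors are retained as
#' provenance. Evaluation is floored at a small positive value so the
#' negative-binomial model stays well defined where the fit returns 0.
#'
#' @param pairs list of 2-column count matrices (each one sample pair),
#'   or a single such matrix.
#' @param min_count size-factor row filter (see
#'   \code{\link{size_factors}}).
#' @param floor minimum dispersion used at evaluation time.
#' @return An object of class \code{"tcr_dispersion"}: list with
#'   \code{a0}, \code{a1}, \code{floor} and \code{provenance} (per-pair
#'   fitted coefficients).
#' @export
median_dispersion_model <- function(pairs, min_count = 5, floor = 1e-8) {
  if (is.matrix(pairs)) pairs <- list(pairs)
  if (!length(pairs)) stop_usage("need at least one sample pair")
  curves <- lapply(pairs, function(m) {
    sf <- size_factors(m, min_count = min_count)
    fit_dispersion_curve(blind_dispersion_estimates(m, sf))
  })
  co <- do.call(rbind, curves)
  structure(list(a0 = stats::median(co[, "a0"]),
                 a1 = stats::median(co[, "a1"]),
                 floor = floor, provenance = curves),
            class = "tcr_dispersion")
}

#' Evaluate a dispersion model at given mean counts
#'
#' @param model a \code{"tcr_dispersion"} object (or a single numeric
#'   dispersion used as a constant).
#' @param mu vector of positive mean normalized counts.
#' @return \eqn{\max(a_0 + a_1/\mu, \mathrm{floor})}.
#' @export
dispersion_at <- function(model, mu) {
  if (is.numeric(model)) return(rep(max(model, 0), length(mu)))
  stopifnot(inherits(model, "tcr_dispersion"))
  pmax(model$a0 + model$a1 / mu, model$floor)
}

#' @export
print.tcr_dispersion <- function(x, ...) {
  cat(sprintf(
    "dispersion model alpha(mu) = %.4g + %.4g/mu (floor %.1g; median of %d curve(s))\n",
    x$a0, x$a1, x$floor, length(x$provenance)))
  invisible(x)
}

# NB pmf; alpha <= 0 is the Poisson limit.
.nb_pmf <- function(x, mu, alpha) {
  if (alpha <= 0) stats::dpois(x, mu) else dnbinom(x, size = 1 / alpha, mu = mu)
}

#' Conditioned negative-binomial exact test for one clonotype
#'
#' The no-replicate two-sample test: under the null the clonotype has a
#' common concentration in both samples, estimated as
#' \eqn{\hat q = (k_A/s_A + k_B/s_B)/2}; counts are modelled as
#' NB with means \eqn{\mu_X = s_X \hat q} and variances
#' \eqn{\mu_X + \alpha(\hat q)\mu_X^2}. Conditioning on the observed sum
#' \eqn{K = k_A + k_B}, the two-sided p-value is the probability-mass
#' ordering over all splits of \eqn{K}:
#' \deqn{p = \frac{\sum_{a : P(a)P(K-a) \le P(k_A)P(k_B)} P(a)P(K-a)}
#'   {\sum_{a=0}^{K} P(a)P(K-a)}}
#' Splits are enumerated exactly up to \code{enum_cap} and accumulated
#' in bounded chunks above it (numerically identical; the off-mode tails
#' contribute negligibly). In the \eqn{\alpha \to 0}, equal-size-factor
#' limit this reduces to the two-sided exact binomial\eqn{(K, 1/2)}
#' test.
#'
#' @param counts integer vector \code{c(k_A, k_B)} with sum >= 1.
#' @param factors size factors \code{c(s_A, s_B)}.
#' @param model a \code{"tcr_dispersion"} model or a single numeric
#'   dispersion \eqn{\alpha}.
#' @param enum_cap chunk size for the split enumeration.
#' @return Two-sided p-value in \eqn{(0, 1]}.
#' @export
nb_exact_test <- function(counts, factors = c(1, 1), model,
                          enum_cap = 1e4) {
  if (length(counts) != 2L || !is_count_vector(counts)) {
    stop_usage("'counts' must be two non-negative integers")
  }
  counts <- round(counts)
  if (sum(counts) < 1) stop_usage("total count must be >= 1")
  if (length(factors) != 2L || any(!is.finite(factors)) ||
      any(factors <= 0)) {
    stop_usage("'factors' must be 2 positive size factors")
  }
  K <- sum(counts)
  qhat <- (counts[1] / factors[1] + counts[2] / factors[2]) / 2
  alpha <- dispersion_at(model, qhat)[1]
  mu_a <- factors[1] * qhat
  mu_b <- factors[2] * qhat
  p_obs <- .nb_pmf(counts[1], mu_a, alpha) * .nb_pmf(counts[2], mu_b, alpha)
  thresh <- p_obs * (1 + 1e-7)  # relative tolerance for pmf ties
  num <- den <- 0
  lo <- 0
  while (lo <= K) {
    a <- lo:min(lo + enum_cap - 1, K)
    pa <- .nb_pmf(a, mu_a, alpha) * .nb_pmf(K - a, mu_b, alpha)
    den <- den + sum(pa)
    num <- num + sum(pa[pa <= thresh])
    lo <- lo + enum_cap
  }
  min(num / den, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1) with input
#' validation; delegates to \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0 | p > 1))) {
    stop_usage("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential clonotype abundance between sample pairs
#'
#' Runs the no-replicate test over one subject's clonotype count matrix
#' for the requested column pairs. Per pair: size factors come from the
#' pair alone (\code{model_scope = "per_pair"}) or from the full matrix
#' (\code{"all_samples"}); the dispersion model is likewise fitted from
#' the pair itself or taken as the median of the curves over all column
#' pairs of the matrix. Every clonotype with a nonzero total in the pair
#' is tested with \code{\link{nb_exact_test}}; log2 fold changes are
#' computed from normalized counts with a 0.5 pseudo-count on zero sides
#' (reporting only — never in the p-value); Benjamini-Hochberg
#' adjustment is applied within each pair's family of tests and the
#' significant set is \code{fdr < fdr_threshold}.
#'
#' @param mat clonotype count matrix (see \code{\link{to_count_matrix}}).
#' @param pairs list of length-2 vectors of column names or indices;
#'   default all column pairs.
#' @param model_scope \code{"per_pair"} or \code{"all_samples"}.
#' @param fdr_threshold significance cutoff on the adjusted p-values.
#' @param min_count size-factor row filter.
#' @param enum_cap passed to \code{\link{nb_exact_test}}.
#' @return An object of class \code{"tcr_difftest"}: a data frame with
#'   columns \code{pair}, \code{clonotype_id}, \code{base_mean},
#'   \code{log2fc}, \code{p_value}, \code{fdr}, \code{direction},
#'   \code{significant}; size factors and the dispersion model(s) are
#'   attached as attributes.
#' @export
run_difftest <- function(mat, pairs = NULL,
                         model_scope = c("per_pair", "all_samples"),
                         fdr_threshold = 0.05, min_count = 5,
                         enum_cap = 1e4) {
  model_scope <- match.arg(model_scope)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_usage("count matrix needs >= 2 columns")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  if (is.null(pairs)) {
    idx <- utils::combn(ncol(mat), 2, simplify = FALSE)
    pairs <- lapply(idx, function(i) colnames(mat)[i])
  }
  pairs <- lapply(pairs, function(pr) {
    if (is.numeric(pr)) pr <- colnames(mat)[pr]
    if (length(pr) != 2L || !all(pr %in% colnames(mat))) {
      stop_usage("each pair must name 2 existing columns")
    }
    pr
  })

  sf_all <- model_all <- NULL
  if (model_scope == "all_samples") {
    sf_all <- size_factors(mat, min_count = min_count)
    all_idx <- utils::combn(ncol(mat), 2, simplify = FALSE)
    curves <- lapply(all_idx, function(i) {
      est <- blind_dispersion_estimates(mat[, i, drop = FALSE], sf_all[i])
      fit_dispersion_curve(est)
    })
    co <- do.call(rbind, curves)
    model_all <- structure(list(a0 = stats::median(co[, "a0"]),
                                a1 = stats::median(co[, "a1"]),
                                floor = 1e-8, provenance = curves),
                           class = "tcr_dispersion")
  }

  sf_used <- list()
  models_used <- list()
  res <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    sub <- mat[, pr, drop = FALSE]
    if (model_scope == "per_pair") {
      sf <- size_factors(sub, min_count = min_count)
      model <- median_dispersion_model(sub, min_count = min_count)
    } else {
      sf <- sf_all[pr]
      model <- model_all
    }
    keep <- rowSums(sub) >= 1
    if (!any(keep)) {
      warning(sprintf("pair %s/%s has no nonzero clonotypes; skipped",
                      pr[1], pr[2]))
      next
    }
    k <- sub[keep, , drop = FALSE]
    q <- sweep(k, 2, sf, "/")
    base_mean <- rowMeans(q)
    # pseudo-count on zero-count sides, for the reported ratio only
    qa <- ifelse(k[, 1] == 0, 0.5 / sf[1], q[, 1])
    qb <- ifelse(k[, 2] == 0, 0.5 / sf[2], q[, 2])
    log2fc <- log2(qb / qa)
    pvals <- vapply(seq_len(nrow(k)), function(i) {
      nb_exact_test(k[i, ], sf, model, enum_cap = enum_cap)
    }, numeric(1))
    fdr <- bh_adjust(pvals)
    res[[pi]] <- data.frame(
      pair = paste(pr, collapse = " vs "),
      clonotype_id = rownames(k) %||% as.character(which(keep)),
      base_mean = base_mean, log2fc = log2fc, p_value = pvals,
      fdr = fdr,
      direction = ifelse(log2fc >= 0, "increase", "decrease"),
      significant = fdr < fdr_threshold,
      stringsAsFactors = FALSE, row.names = NULL)
    sf_used[[paste(pr, collapse = " vs ")]] <- sf
    models_used[[paste(pr, collapse = " vs ")]] <- model
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  structure(out, size_factors = sf_used, dispersion = models_used,
            model_scope = model_scope, fdr_threshold = fdr_threshold,
            class = c("tcr_difftest", "data.frame"))
}

#' @export
print.tcr_difftest <- function(x, ...) {
  thr <- attr(x, "fdr_threshold")
  cat(sprintf("differential clonotype abundance (%s scope, FDR < %g)\n",
              attr(x, "model_scope"), thr))
  for (pr in unique(x$pair)) {
    sub <- x[x$pair == pr, ]
    sig <- sub[sub$significant, ]
    cat(sprintf("  %s: %d tested, %d significant (%d increase, %d decrease)\n",
                pr, nrow(sub), nrow(sig),
                sum(sig$direction == "increase"),
                sum(sig$direction == "decrease")))
  }
  invisible(x)
}

#' @export
summary.tcr_difftest <- function(object, ...) {
  do.call(rbind, lapply(unique(object$pair), function(pr) {
    sub <- object[object$pair == pr, ]
    sig <- sub[sub$significant, ]
    data.frame(pair = pr, n_tested = nrow(sub), n_significant = nrow(sig),
               n_increase = sum(sig$direction == "increase"),
               n_decrease = sum(sig$direction == "decrease"),
               stringsAsFactors = FALSE)
  }))
}

#' Tissue presence of significantly changed clones
#'
#' Given a differential-test result for blood sample pairs and a tissue
#' repertoire from the same subject, flags each significant clone's
#' presence in the tissue, tabulates counts and fractions by direction
#' of change, and compares the \eqn{\log_{10}} tissue counts of the
#' significant-and-present clones against the mean \eqn{\log_{10}}
#' count of all tissue-present clones with a two-sided one-sample
#' t-test. A significant set whose tissue counts sit above the overall
#' mean is what treatment-induced trafficking of expanded blood clones
#' into the tissue would produce.
#'
#' @param result a \code{\link{run_difftest}} result (one or more
#'   pairs; summarized jointly).
#' @param tissue the tissue \code{\link{tcr_repertoire}}.
#' @return An object of class \code{"tcr_tissue_summary"}: list with
#'   \code{n_significant}, \code{n_present}, \code{fraction_present},
#'   \code{by_direction} (counts and presence fractions),
#'   \code{log10_tissue_counts} (significant-and-present clones),
#'   \code{overall_mean_log10} (all tissue clones), \code{p_value}
#'   (NA when fewer than 2 clones can be tested) and the flagged
#'   \code{table}.
#' @export
tissue_presence_summary <- function(result, tissue) {
  stopifnot(inherits(result, "tcr_difftest"),
            inherits(tissue, "tcr_repertoire"))
  sig <- result[result$significant, , drop = FALSE]
  overall_mean <- mean(log10(tissue$tab$count))
  if (nrow(sig) == 0L) {
    return(structure(list(n_significant = 0L, n_present = 0L,
                          fraction_present = 0,
                          by_direction = NULL,
                          log10_tissue_counts = numeric(0),
                          overall_mean_log10 = overall_mean,
                          p_value = NA_real_,
                          table = sig),
                     class = "tcr_tissue_summary"))
  }
  hit <- match(sig$clonotype_id, tissue$tab$clonotype_id)
  sig$tissue_present <- !is.na(hit)
  sig$tissue_count <- ifelse(sig$tissue_present, tissue$tab$count[hit], NA)
  by_dir <- do.call(rbind, lapply(split(sig, sig$direction), function(d) {
    data.frame(direction = d$direction[1], n = nrow(d),
               n_present = sum(d$tissue_present),
               fraction_present = mean(d$tissue_present),
               stringsAsFactors = FALSE)
  }))
  x <- log10(sig$tissue_count[sig$tissue_present])
  pv <- if (length(x) >= 2L && stats::sd(x) > 0) {
    stats::t.test(x, mu = overall_mean)$p.value
  } else {
    NA_real_
  }
  structure(list(n_significant = nrow(sig),
                 n_present = sum(sig$tissue_present),
                 fraction_present = mean(sig$tissue_present),
                 by_direction = by_dir,
                 log10_tissue_counts = x,
                 overall_mean_log10 = overall_mean,
                 p_value = pv,
                 table = sig),
            class = "tcr_tissue_summary")
}

#' @export
print.tcr_tissue_summary <- function(x, ...) {
  cat(sprintf(
    "tissue presence of significant clones: %d/%d (%.1f%%) present\n",
    x$n_present, x$n_significant, 100 * x$fraction_present))
  if (!is.null(x$by_direction)) print(x$by_direction, row.names = FALSE)
  if (length(x$log10_tissue_counts)) {
    cat(sprintf(
      "  mean log10 tissue count of significant clones %.3f vs overall %.3f (p = %s)\n",
      mean(x$log10_tissue_counts), x$overall_mean_log10,
      format.pval(x$p_value, digits = 3)))
  }
  invisible(x)
}
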