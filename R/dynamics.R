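# Between-sample dynamics: binary similarity, Morisita overlap, relative
# clonality, one-way random-effects ICC, fold-change analysis.

#' Jaccard similarity from a presence summary
#'
#' \eqn{J = n_{12} / (n_1 + n_2 - n_{12})}: the fraction of the pair's
#' pooled clonotypes present in both samples.
#'
#' @param ps a \code{\link{presence_summary}}.
#' @return Jaccard coefficient in \eqn{[0, 1]}.
#' @export
jaccard_index <- function(ps) {
  stopifnot(inherits(ps, "tcr_presence"))
  denom <- ps$n1 + ps$n2 - ps$n12
  if (denom <= 0) stop_usage("Jaccard undefined: both samples empty")
  ps$n12 / denom
}

#' Baroni-Urbani & Buser binary similarity
#'
#' \deqn{BUB = \frac{n_{12} + \sqrt{n_{12} d_{12}}}{n_1 + n_2 - n_{12} +
#'   \sqrt{n_{12} d_{12}}}}
#' Unlike most overlap measures, BUB credits the negative matches
#' \eqn{d_{12}} — clones absent from both samples but present elsewhere
#' in the declared universe — which makes the pairwise values comparable
#' across pairs drawn from the same universe (e.g. three serial samples
#' of one subject). With \eqn{d_{12} = 0} (a pair-only universe) it
#' reduces exactly to the Jaccard coefficient.
#'
#' @inheritParams jaccard_index
#' @return BUB similarity in \eqn{[0, 1]}.
#' @export
bub_index <- function(ps) {
  stopifnot(inherits(ps, "tcr_presence"))
  root <- sqrt(ps$n12 * ps$d12)
  denom <- ps$n1 + ps$n2 - ps$n12 + root
  if (denom <= 0) stop_usage("BUB undefined: empty universe pair")
  (ps$n12 + root) / denom
}

#' Second Baroni-Urbani & Buser coefficient
#'
#' \deqn{BUB_2 = \frac{3 n_{12} - (n_1 + n_2) + \sqrt{n_{12} d_{12}}}{n_1
#'   + n_2 - n_{12} + \sqrt{n_{12} d_{12}}}}
#' A correlation-like variant of \code{\link{bub_index}} ranging over
#' \eqn{[-1, 1]}; disjoint samples give \eqn{-1}.
#'
#' @inheritParams jaccard_index
#' @export
bub2_index <- function(ps) {
  stopifnot(inherits(ps, "tcr_presence"))
  root <- sqrt(ps$n12 * ps$d12)
  denom <- ps$n1 + ps$n2 - ps$n12 + root
  if (denom <= 0) stop_usage("BUB2 undefined: empty universe pair")
  (3 * ps$n12 - (ps$n1 + ps$n2) + root) / denom
}

#' Morisita overlap index between two repertoires
#'
#' The abundance-weighted overlap
#' \deqn{C_D = \frac{2 \sum_i f_{ij} f_{ik}}{\left(\frac{\sum_i
#'   f_{ij}^2}{F_j^2} + \frac{\sum_i f_{ik}^2}{F_k^2}\right) F_j F_k}}
#' summed over the union of clonotypes (a clone absent from one sample
#' contributes count 0, leaving the sums unchanged), where \eqn{f_{ij}}
#' is the count of clone \eqn{i} in sample \eqn{j} and \eqn{F_j} the
#' read depth. \eqn{C_D = 0} when the samples share no clonotypes and
#' \eqn{C_D = 1} when the clonotypes occur in identical proportions in
#' both samples; it is invariant to proportional rescaling of either
#' sample's counts. (This is the Morisita-Horn form.)
#'
#' @param a,b two \code{\link{tcr_repertoire}} samples.
#' @return Overlap in \eqn{[0, 1]}.
#' @examples
#' s1 <- tcr_repertoire(c("x", "y"), c(10, 10))
#' s2 <- tcr_repertoire(c("x", "y"), c(5, 15))
#' morisita_overlap(s1, s2)  # 400/450
#' @export
morisita_overlap <- function(a, b) {
  stopifnot(inherits(a, "tcr_repertoire"), inherits(b, "tcr_repertoire"))
  ids <- union(a$tab$clonotype_id, b$tab$clonotype_id)
  fa <- fb <- numeric(length(ids))
  names(fa) <- names(fb) <- ids
  fa[a$tab$clonotype_id] <- a$tab$count
  fb[b$tab$clonotype_id] <- b$tab$count
  Fa <- a$read_depth
  Fb <- b$read_depth
  num <- 2 * sum(fa * fb)
  den <- (sum(fa^2) / Fa^2 + sum(fb^2) / Fb^2) * Fa * Fb
  num / den
}

#' Relative clonality between two time points
#'
#' \eqn{RCL = \mathrm{clonality}(later) / \mathrm{clonality}(earlier)}:
#' values above 1 indicate a repertoire that became more restricted.
#' Antisymmetric under swapping the pair (the ratio inverts).
#'
#' @param later,earlier \code{\link{tcr_repertoire}} samples; the ratio
#'   is later over earlier.
#' @return A positive ratio.
#' @export
relative_clonality <- function(later, earlier) {
  cl_e <- clonality(earlier)
  if (cl_e <= 0) {
    stop_usage("relative clonality undefined: earlier sample has clonality 0")
  }
  clonality(later) / cl_e
}

#' Log10 frequency matrix over a sample set
#'
#' Builds the clonotype-by-sample matrix of \eqn{z_{ij} = \log_{10}
#' p_{ij}} consumed by \code{\link{icc_oneway}}. The default
#' \code{"common"} scope restricts rows to clonotypes present in every
#' sample — appropriate because clones absent from some samples would
#' otherwise dominate the concordance — while \code{"union"} keeps all
#' clonotypes and imputes an absent clone's frequency as half a count,
#' \eqn{0.5 / F_j}.
#'
#' @param samples list of >= 2 \code{\link{tcr_repertoire}} objects.
#' @param scope \code{"common"} (default) or \code{"union"}.
#' @return A numeric matrix (clonotypes x samples) of log10 frequencies.
#' @export
log_frequency_matrix <- function(samples, scope = c("common", "union")) {
  scope <- match.arg(scope)
  stopifnot(is.list(samples), length(samples) >= 2L)
  id_sets <- lapply(samples, function(s) s$tab$clonotype_id)
  ids <- if (scope == "common") {
    Reduce(intersect, id_sets)
  } else {
    sort(unique(unlist(id_sets)))
  }
  if (length(ids) < 2L) {
    stop_usage("fewer than 2 clonotypes in '%s' scope", scope)
  }
  ids <- sort(ids)
  z <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, vapply(samples,
                                          function(s) s$sample_id,
                                          character(1))))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    freq <- rep(0.5 / s$read_depth, length(ids))
    hit <- match(ids, s$tab$clonotype_id)
    freq[!is.na(hit)] <- s$tab$frequency[hit[!is.na(hit)]]
    z[, j] <- log10(freq)
  }
  z
}

#' One-way random-effects intraclass correlation
#'
#' Fits the one-way random-effects model with clonotypes as subjects
#' (rows) and samples as repeated measurements (columns) and returns the
#' single-rater consistency
#' \deqn{ICC(1,1) = \frac{MS_B - MS_W}{MS_B + (k - 1) MS_W}}
#' from the one-way ANOVA decomposition over \eqn{k} columns, together
#' with the variance components \eqn{S_a^2 = (MS_B - MS_W)/k} (between
#' clonotypes) and \eqn{S_e^2 = MS_W} (residual), so that
#' \eqn{ICC = S_a^2 / (S_a^2 + S_e^2)}. Applied to a log10 frequency
#' matrix (\code{\link{log_frequency_matrix}}) this measures how
#' strongly the common clones' abundances agree across time points or
#' compartments: identical columns give exactly 1.
#'
#' @param z numeric matrix with >= 2 rows (clonotypes) and >= 2 columns
#'   (samples), no missing cells; typically
#'   \code{log_frequency_matrix(samples, scope = "common")}.
#' @return An object of class \code{"tcr_icc"}: list with \code{icc},
#'   \code{s2_a}, \code{s2_e}, \code{msb}, \code{msw}, \code{n}
#'   (clonotypes) and \code{k} (samples).
#' @examples
#' z <- rbind(c(1, 2), c(2, 3), c(3, 4))
#' icc_oneway(z)$icc   # 0.6
#' @export
icc_oneway <- function(z) {
  z <- as.matrix(z)
  if (!is.numeric(z) || anyNA(z)) {
    stop_usage("'z' must be a numeric matrix without missing values")
  }
  n <- nrow(z)
  k <- ncol(z)
  if (n < 2L || k < 2L) {
    stop_usage("ICC needs at least 2 clonotypes and 2 samples (got %dx%d)",
               n, k)
  }
  row_means <- rowMeans(z)
  grand <- mean(z)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((z - row_means)^2) / (n * (k - 1))
  icc <- if (msb == 0 && msw == 0) 1 else (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, s2_a = (msb - msw) / k, s2_e = msw,
                 msb = msb, msw = msw, n = n, k = k),
            class = "tcr_icc")
}

#' @export
print.tcr_icc <- function(x, digits = 4, ...) {
  cat(sprintf(
    "one-way random-effects ICC(1,1): %.*f  (S_a^2 %.4g, S_e^2 %.4g; %d clones x %d samples)\n",
    digits, x$icc, x$s2_a, x$s2_e, x$n, x$k))
  invisible(x)
}

#' Per-clonotype log2 fold changes between two samples
#'
#' \eqn{FC_i = \log_2(p_{ik} / p_{ij})} for each scored clonotype, where
#' \eqn{j} is the earlier (\code{from}) and \eqn{k} the later
#' (\code{to}) sample. Scope \code{"overlap"} scores only clones present
#' in both samples; scope \code{"union"} scores every clone present in
#' either, imputing an absent clone's frequency as
#' \code{zero_impute / read_depth} of its sample (default half a count,
#' which preserves the direction of change without infinities).
#'
#' @param from,to \code{\link{tcr_repertoire}} samples (earlier, later).
#' @param scope \code{"overlap"} (default) or \code{"union"}.
#' @param zero_impute pseudo-count used for absent clones under the
#'   union scope.
#' @return An object of class \code{"tcr_foldchange"}: a data frame with
#'   columns \code{clonotype_id}, \code{p_from}, \code{p_to}, \code{fc},
#'   plus attributes \code{scope} and \code{pair}. Empty overlap returns
#'   a zero-row result flagged via attribute \code{"empty"}.
#' @export
fold_changes <- function(from, to, scope = c("overlap", "union"),
                         zero_impute = 0.5) {
  scope <- match.arg(scope)
  stopifnot(inherits(from, "tcr_repertoire"),
            inherits(to, "tcr_repertoire"))
  if (scope == "overlap") {
    ids <- intersect(from$tab$clonotype_id, to$tab$clonotype_id)
  } else {
    ids <- union(from$tab$clonotype_id, to$tab$clonotype_id)
  }
  ids <- sort(ids)
  lookup <- function(s, ids) {
    freq <- rep(zero_impute / s$read_depth, length(ids))
    hit <- match(ids, s$tab$clonotype_id)
    freq[!is.na(hit)] <- s$tab$frequency[hit[!is.na(hit)]]
    freq
  }
  p_from <- lookup(from, ids)
  p_to <- lookup(to, ids)
  out <- data.frame(clonotype_id = ids, p_from = p_from, p_to = p_to,
                    fc = log2(p_to / p_from), stringsAsFactors = FALSE)
  structure(out, scope = scope,
            pair = c(from$sample_id, to$sample_id),
            empty = nrow(out) == 0L,
            class = c("tcr_foldchange", "data.frame"))
}

#' Bin fold changes into decrease / unchanged / increase
#'
#' Partitions the scored clonotypes by the symmetric cutoff \eqn{c > 0}:
#' decrease when \eqn{FC \le -c}, unchanged when \eqn{-c < FC < c},
#' increase when \eqn{FC \ge c} (boundaries inclusive on the
#' decrease/increase sides). With \eqn{c = 2} the bins correspond to
#' frequency ratios below 1/4, between 1/4 and 4, and above 4.
#'
#' @param fc a \code{\link{fold_changes}} result (or a bare numeric
#'   vector of log2 fold changes).
#' @param c positive cutoff on the log2 scale; when comparing different
#'   biological compartments use \code{\link{compartment_adjusted_c}}.
#' @return A list of class \code{"tcr_fc_bins"} with integer
#'   \code{counts} and \code{fractions} over the three bins, plus
#'   \code{c} and \code{n}.
#' @export
bin_fold_changes <- function(fc, c = 2) {
  assert_scalar_number(c, "c")
  if (c <= 0) stop_usage("'c' must be > 0")
  vals <- if (is.data.frame(fc)) fc$fc else as.numeric(fc)
  counts <- c(decrease = sum(vals <= -c),
              unchanged = sum(vals > -c & vals < c),
              increase = sum(vals >= c))
  n <- length(vals)
  structure(list(counts = counts,
                 fractions = if (n > 0) counts / n else counts * NA_real_,
                 c = c, n = n),
            class = "tcr_fc_bins")
}

#' @export
print.tcr_fc_bins <- function(x, ...) {
  cat(sprintf("fold-change bins (c = %g, %d clones):\n", x$c, x$n))
  print(rbind(count = x$counts, fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Compartment-adjusted fold-change cutoff
#'
#' When the two samples come from different biological compartments
#' (e.g. blood PBMC vs prostate tissue), systematic depth and
#' composition differences shift the whole fold-change distribution. The
#' cutoff is rescaled by the ratio of summed log2 frequencies over the
#' \eqn{m} clones common to the pair:
#' \deqn{c' = c \times \frac{\sum_{i=1}^m \log_2 p_{ik}}{\sum_{i=1}^m
#'   \log_2 p_{ij}}}
#' Both sums are negative for valid frequencies, so the adjusted cutoff
#' stays positive; identical frequency profiles leave \eqn{c} unchanged.
#'
#' @inheritParams fold_changes
#' @param c baseline cutoff (> 0).
#' @return The adjusted cutoff, a positive number.
#' @export
compartment_adjusted_c <- function(from, to, c = 2) {
  assert_scalar_number(c, "c")
  if (c <= 0) stop_usage("'c' must be > 0")
  ids <- intersect(from$tab$clonotype_id, to$tab$clonotype_id)
  if (length(ids) == 0L) {
    stop_usage("no common clones: compartment adjustment undefined")
  }
  p_from <- from$tab$frequency[match(ids, from$tab$clonotype_id)]
  p_to <- to$tab$frequency[match(ids, to$tab$clonotype_id)]
  den <- sum(log2(p_from))
  if (den == 0) {
    stop_usage("adjustment undefined: log-frequency sum is zero")
  }
  c * sum(log2(p_to)) / den
}

#' All pairwise dynamics measures for one sample pair
#'
#' Convenience wrapper computing the binary similarities (within the
#' declared universe), Morisita overlap, relative clonality (second over
#' first) and the common-clone ICC for one pair.
#'
#' @param a,b the pair of \code{\link{tcr_repertoire}} samples
#'   (\code{a} earlier, \code{b} later).
#' @param universe universe for \code{\link{presence_summary}}; defaults
#'   to the pair.
#' @return A one-row data frame with the measures; ICC is \code{NA} when
#'   fewer than two common clones exist.
#' @export
pairwise_dynamics <- function(a, b, universe = list(a, b)) {
  ps <- presence_summary(a, b, universe)
  icc <- tryCatch(
    icc_oneway(log_frequency_matrix(list(a, b), scope = "common"))$icc,
    error = function(e) NA_real_)
  rcl <- tryCatch(relative_clonality(b, a), error = function(e) NA_real_)
  data.frame(sample_1 = a$sample_id, sample_2 = b$sample_id,
             jaccard = jaccard_index(ps), bub = bub_index(ps),
             bub2 = bub2_index(ps), morisita = morisita_overlap(a, b),
             relative_clonality = rcl, icc = icc,
             stringsAsFactors = FALSE)
}
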