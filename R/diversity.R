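# Per-sample diversity indices. All entropies use the natural logarithm.

# Accept either a tcr_repertoire or a bare frequency vector; validate.
.freqs <- function(x, check_sum = TRUE) {
  p <- if (inherits(x, "tcr_repertoire")) x$tab$frequency else as.numeric(x)
  if (length(p) == 0L) stop_usage("empty sample: no frequencies")
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop_usage("frequencies must be finite and > 0")
  }
  if (check_sum && abs(sum(p) - 1) > 1e-9) {
    stop_usage("frequencies must sum to 1 (got %.12f)", sum(p))
  }
  p
}

#' Shannon entropy of a clonotype frequency distribution
#'
#' \eqn{H = -\sum_i p_i \log_e p_i}, in nats. A monoclonal sample
#' (single clonotype) has \eqn{H = 0}.
#'
#' @param x a \code{\link{tcr_repertoire}} or a numeric vector of
#'   clonotype frequencies summing to 1.
#' @return Shannon entropy in nats.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # log(4)
#' @export
shannon_entropy <- function(x) {
  p <- .freqs(x)
  -sum(p * log(p))
}

#' Renyi entropy of order a
#'
#' \eqn{H_a = \frac{1}{1-a}\log_e \sum_i p_i^a}. The family is evaluated
#' by its analytic limits at the special orders: \eqn{a = 1} returns the
#' Shannon entropy and \eqn{a = \infty} returns \eqn{-\log_e \max p_i}.
#' \eqn{H_0 = \log_e n} is the log richness. Renyi entropy is
#' non-increasing in \eqn{a}, so one sample can be called more diverse
#' than another when its whole Renyi profile lies above the other's.
#'
#' @inheritParams shannon_entropy
#' @param order a single order \eqn{a \ge 0}; \code{Inf} is allowed.
#' @return Renyi entropy in nats.
#' @export
renyi_entropy <- function(x, order) {
  p <- .freqs(x)
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order < 0) {
    stop_usage("'order' must be a single number >= 0")
  }
  if (is.infinite(order)) return(-log(max(p)))
  if (order == 1) return(-sum(p * log(p)))
  log(sum(p^order)) / (1 - order)
}

#' Hill number of order a
#'
#' \eqn{N_a = \exp(H_a)}, the effective number of clonotypes. Special
#' cases: \eqn{N_0 = n} (richness), \eqn{N_1 = \exp(H)},
#' \eqn{N_2 = D_2} (inverse Simpson) and
#' \eqn{N_\infty = 1/\max p_i} (dominance).
#'
#' @inheritParams renyi_entropy
#' @return Hill number (>= 1).
#' @export
hill_number <- function(x, order) {
  if (is.numeric(order) && length(order) == 1L && !is.na(order) &&
      order == 0) {
    # exp(log(n)) can be off by an ulp; richness is an exact integer
    return(as.numeric(length(.freqs(x))))
  }
  exp(renyi_entropy(x, order))
}

#' Gini-Simpson index
#'
#' \eqn{D_1 = 1 - \sum_i p_i^2}, in \eqn{[0, 1)}.
#'
#' @inheritParams shannon_entropy
#' @export
gini_simpson <- function(x) {
  p <- .freqs(x)
  1 - sum(p^2)
}

#' Inverse Simpson index
#'
#' \eqn{D_2 = 1 / \sum_i p_i^2}, in \eqn{[1, n]}; equals the Hill number
#' of order 2.
#'
#' @inheritParams shannon_entropy
#' @export
inverse_simpson <- function(x) {
  p <- .freqs(x)
  1 / sum(p^2)
}

#' Pielou evenness
#'
#' \eqn{J = H / \log_e n}, in \eqn{[0, 1]}. For a monoclonal sample
#' (\eqn{n = 1}) the ratio is 0/0; the convention \eqn{J = 0} is used so
#' that \code{clonality} stays the complement of evenness.
#'
#' @inheritParams shannon_entropy
#' @export
pielou_evenness <- function(x) {
  p <- .freqs(x)
  n <- length(p)
  if (n == 1L) return(0)
  -sum(p * log(p)) / log(n)
}

#' Clonality
#'
#' \eqn{\mathrm{Clonality} = 1 - H/\log_e n}: 0 for a maximally even
#' repertoire, 1 for a monoclonal one. The \eqn{n = 1} case is 0/0 and
#' is defined as 1 by convention — a monoclonal repertoire is the
#' extreme of the restricted-repertoire state the index measures.
#' Clonality is invariant under uniform scaling of all counts, which is
#' what makes it comparatively robust to count-threshold filtering.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in \eqn{[0, 1]}.
#' @export
clonality <- function(x) {
  1 - pielou_evenness(x)
}

#' Geometric coefficient of variation of log10 clone frequencies
#'
#' Clone frequencies are heavily right-skewed, so dispersion is measured
#' on \eqn{\log_{10} p_i}. Let \eqn{S} be the sample standard deviation
#' (denominator \eqn{n - 1}) of \eqn{\log_{10} p_i}. Two forms are
#' available:
#' \describe{
#'   \item{\code{canonical}}{Kirkwood's geometric CV on the natural-log
#'     scale, \eqn{\exp(S \log_e 10) - 1}, which is 0 for a sample with
#'     zero dispersion (all frequencies equal) as a coefficient of
#'     variation must be.}
#'   \item{\code{as_printed}}{\eqn{\exp(S_{ln} - 1)} with
#'     \eqn{S_{ln} = S \times 10 \times \log_e 10}, a variant circulating
#'     in the repertoire literature; note it returns \eqn{e^{-1}} for
#'     zero dispersion, so it is not a CV in the strict sense. It is kept
#'     behind this mode flag for comparability.}
#' }
#'
#' @param x a \code{\link{tcr_repertoire}} or a numeric vector of
#'   positive frequencies (need not sum to 1).
#' @param mode \code{"canonical"} (default) or \code{"as_printed"}.
#' @return The geometric CV (a non-negative number in canonical mode).
#' @export
geometric_cv <- function(x, mode = c("canonical", "as_printed")) {
  mode <- match.arg(mode)
  p <- .freqs(x, check_sum = FALSE)
  if (length(p) < 2L) {
    stop_usage("geometric CV needs at least 2 clonotypes (sd undefined)")
  }
  s <- stats::sd(log10(p))
  if (mode == "canonical") {
    exp(s * log(10)) - 1
  } else {
    exp(s * 10 * log(10) - 1)
  }
}

#' Full diversity profile of a repertoire sample
#'
#' Computes every per-sample diversity index at once: richness and read
#' depth, Shannon entropy, Renyi entropies and Hill numbers over the
#' requested orders, Gini-Simpson, inverse Simpson, Pielou evenness,
#' clonality and the geometric CV (with the underlying \eqn{S} and
#' \eqn{S_{ln}} retained).
#'
#' @param x a \code{\link{tcr_repertoire}}.
#' @param orders numeric vector of Renyi/Hill orders (\code{Inf}
#'   allowed).
#' @param gcv_mode passed to \code{\link{geometric_cv}}.
#' @return An object of class \code{"tcr_diversity"}; a list whose
#'   \code{renyi} and \code{hill} elements are named numeric vectors
#'   keyed by order.
#' @examples
#' rep <- tcr_repertoire(letters[1:4], c(10, 10, 10, 10))
#' prof <- diversity_profile(rep)
#' prof$clonality      # 0: perfectly even
#' prof$hill[["2"]]    # 4: effective number of clones
#' @export
diversity_profile <- function(x, orders = c(0, 1, 2, Inf),
                              gcv_mode = c("canonical", "as_printed")) {
  stopifnot(inherits(x, "tcr_repertoire"))
  gcv_mode <- match.arg(gcv_mode)
  p <- .freqs(x)
  ren <- vapply(orders, function(a) renyi_entropy(p, a), numeric(1))
  names(ren) <- as.character(orders)
  hill <- exp(ren)
  hill[names(hill) == "0"] <- length(p)  # exact richness
  s <- if (length(p) >= 2L) stats::sd(log10(p)) else NA_real_
  out <- list(
    sample_id = x$sample_id,
    n_unique = x$n_unique,
    read_depth = x$read_depth,
    threshold = x$threshold,
    shannon = shannon_entropy(p),
    renyi = ren,
    hill = hill,
    gini_simpson = gini_simpson(p),
    inverse_simpson = inverse_simpson(p),
    evenness = pielou_evenness(p),
    clonality = clonality(p),
    gcv = if (length(p) >= 2L) geometric_cv(p, gcv_mode) else NA_real_,
    gcv_mode = gcv_mode,
    sd_log10 = s,
    s_ln = if (is.na(s)) NA_real_ else s * 10 * log(10)
  )
  class(out) <- "tcr_diversity"
  out
}

#' @export
print.tcr_diversity <- function(x, digits = 4, ...) {
  cat(sprintf("Diversity profile of '%s' (min count %d)\n", x$sample_id,
              x$threshold))
  cat(sprintf("  n_unique %d, read depth %s\n", x$n_unique,
              format(x$read_depth, big.mark = ",")))
  cat(sprintf("  Shannon %.*f | clonality %.*f | evenness %.*f\n",
              digits, x$shannon, digits, x$clonality, digits, x$evenness))
  cat(sprintf("  Gini-Simpson %.*f | inverse Simpson %.*f | GCV (%s) %.*f\n",
              digits, x$gini_simpson, digits, x$inverse_simpson,
              x$gcv_mode, digits, x$gcv))
  cat("  Hill numbers:\n")
  print(round(x$hill, digits))
  invisible(x)
}

#' @export
as.data.frame.tcr_diversity <- function(x, ...) {
  base <- data.frame(
    sample_id = x$sample_id, threshold = x$threshold,
    index = c("n_unique", "read_depth", "shannon", "gini_simpson",
              "inverse_simpson", "evenness", "clonality", "gcv",
              paste0("hill_", names(x$hill))),
    value = c(x$n_unique, x$read_depth, x$shannon, x$gini_simpson,
              x$inverse_simpson, x$evenness, x$clonality, x$gcv,
              unname(x$hill)),
    stringsAsFactors = FALSE)
  base
}

#' Count-threshold robustness sweep of the diversity indices
#'
#' Refilters the sample at each minimum-count threshold, recomputes the
#' clone frequencies over the retained clonotypes, and recomputes the
#' full diversity profile — the robustness analysis that asks which
#' indices are stable when low-count clones are progressively removed
#' (clonality typically is; richness by construction is not). A
#' threshold that empties the sample yields a profile flagged undefined
#' rather than an error.
#'
#' @param x a \code{\link{tcr_repertoire}}.
#' @param thresholds ascending positive integer thresholds; the default
#'   \code{c(2, 5, 10, 15, 20, 25, 30)} spans the cutoffs in routine use.
#' @param orders,gcv_mode passed to \code{\link{diversity_profile}}.
#' @return An object of class \code{"tcr_sweep"}: a list of
#'   \code{tcr_diversity} profiles (an emptied threshold contributes
#'   \code{NULL} with an attribute marking it undefined); use
#'   \code{as.data.frame} for the long-format table.
#' @export
threshold_sweep <- function(x, thresholds = c(2, 5, 10, 15, 20, 25, 30),
                            orders = c(0, 1, 2, Inf),
                            gcv_mode = c("canonical", "as_printed")) {
  stopifnot(inherits(x, "tcr_repertoire"))
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop_usage("'thresholds' must be sorted ascending")
  }
  if (any(thresholds < 1)) stop_usage("thresholds must be >= 1")
  gcv_mode <- match.arg(gcv_mode)
  profiles <- vector("list", length(thresholds))
  undefined <- logical(length(thresholds))
  for (i in seq_along(thresholds)) {
    filt <- tryCatch(filter_by_count(x, thresholds[i]),
                     error = function(e) NULL)
    if (is.null(filt)) {
      undefined[i] <- TRUE
    } else {
      profiles[[i]] <- diversity_profile(filt, orders = orders,
                                         gcv_mode = gcv_mode)
    }
  }
  structure(list(sample_id = x$sample_id, thresholds = thresholds,
                 profiles = profiles, undefined = undefined),
            class = "tcr_sweep")
}

#' @export
as.data.frame.tcr_sweep <- function(x, ...) {
  keep <- !x$undefined
  if (!any(keep)) {
    return(data.frame(sample_id = character(), threshold = integer(),
                      index = character(), value = numeric()))
  }
  do.call(rbind, lapply(x$profiles[keep], as.data.frame))
}

#' @export
print.tcr_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep of '%s' over min counts %s\n", x$sample_id,
              paste(x$thresholds, collapse = ", ")))
  df <- as.data.frame(x)
  wide <- stats::reshape(df[df$index %in% c("n_unique", "shannon",
                                            "clonality"), ],
                         idvar = "threshold", timevar = "index",
                         drop = "sample_id", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (any(x$undefined)) {
    cat("  undefined (sample emptied) at thresholds:",
        paste(x$thresholds[x$undefined], collapse = ", "), "\n")
  }
  invisible(x)
}
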