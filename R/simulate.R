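# Seeded synthetic repertoire generators. These emulate the statistical
# structure real clonotype tables exhibit: clone-abundance distributions
# heavily skewed towards rare clonotypes (many observed once), partial
# clone sharing between serial samples of a subject, and optional
# treatment-like enrichment of a clone subset.

#' Abundance laws for the repertoire simulator
#'
#' \code{power_law(exponent)}: true clone frequencies proportional to
#' \eqn{k^{-\gamma}} over ranks \eqn{k = 1..n}; the default
#' \eqn{\gamma = 2} produces the singleton-heavy shape of real
#' repertoires at typical sequencing depths.
#' \code{log_series(theta)}: Fisher log-series weights
#' \eqn{\theta^k / k}.
#'
#' @param exponent power-law exponent \eqn{\gamma > 0}.
#' @param theta log-series parameter in \eqn{(0, 1)}.
#' @return A law description consumed by \code{\link{simulation_spec}}.
#' @export
power_law <- function(exponent = 2) {
  assert_scalar_number(exponent, "exponent")
  if (exponent <= 0) stop_usage("power-law exponent must be > 0")
  list(law = "power_law", exponent = exponent)
}

#' @rdname power_law
#' @export
log_series <- function(theta = 0.999) {
  assert_scalar_number(theta, "theta")
  if (theta <= 0 || theta >= 1) stop_usage("theta must be in (0, 1)")
  list(law = "log_series", theta = theta)
}

#' Specification of a synthetic repertoire
#'
#' Collects every parameter of the generator so that one seed fully
#' determines the output. Defaults describe a typical bulk TCR-beta
#' sequencing experiment: 5,000 true clones under a rank power law with
#' exponent 2, 100,000 reads, and 80% of clones persisting between
#' serial time points of the same subject.
#'
#' @param n_clones number of true clones in the subject's repertoire.
#' @param abundance_law \code{\link{power_law}} or \code{\link{log_series}}.
#' @param read_depth total reads drawn per sample (multinomial total).
#' @param shared_fraction fraction of clones persisting across time
#'   points in \code{\link{simulate_timecourse}}.
#' @param spike optional treatment-like enrichment, see
#'   \code{\link{spike_spec}}.
#' @param seed integer RNG seed; the same spec always yields the same
#'   samples.
#' @return A list of class \code{"sim_spec"}.
#' @export
simulation_spec <- function(n_clones = 5000, abundance_law = power_law(2),
                            read_depth = 1e5, shared_fraction = 0.8,
                            spike = NULL, seed = 1) {
  assert_scalar_number(n_clones, "n_clones", lower = 2)
  assert_scalar_number(read_depth, "read_depth", lower = 1)
  assert_scalar_number(shared_fraction, "shared_fraction", lower = 0)
  if (shared_fraction > 1) stop_usage("shared_fraction must be <= 1")
  assert_scalar_number(seed, "seed")
  if (!is.list(abundance_law) ||
      !abundance_law$law %in% c("power_law", "log_series")) {
    stop_usage("abundance_law must come from power_law() or log_series()")
  }
  if (!is.null(spike) && !inherits(spike, "spike_spec")) {
    stop_usage("spike must come from spike_spec()")
  }
  structure(list(n_clones = as.integer(n_clones),
                 abundance_law = abundance_law,
                 read_depth = as.integer(read_depth),
                 shared_fraction = shared_fraction,
                 spike = spike, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Treatment-like enrichment of a clone subset
#'
#' At post-baseline time points of \code{\link{simulate_timecourse}},
#' the true frequencies of the spiked clones are multiplied by
#' \code{fold} and the frequency vector renormalized.
#'
#' @param n_spiked number of enriched clones.
#' @param fold enrichment factor (> 0).
#' @param placement where the spiked clones sit in the abundance
#'   ranking: drawn from the top quartile of true frequencies
#'   (\code{"top_quartile"}) or uniformly over the shared clones
#'   (\code{"uniform"}). Ignored when \code{clones} is given.
#' @param clones optional explicit clone indices (ranks in the
#'   abundance law) to spike, e.g. to target clones whose expected
#'   baseline count clears a detection floor.
#' @return A list of class \code{"spike_spec"}.
#' @export
spike_spec <- function(n_spiked, fold,
                       placement = c("top_quartile", "uniform"),
                       clones = NULL) {
  placement <- match.arg(placement)
  assert_scalar_number(n_spiked, "n_spiked", lower = 1)
  assert_scalar_number(fold, "fold")
  if (fold <= 0) stop_usage("spike fold must be > 0")
  if (!is.null(clones) && !is_count_vector(clones)) {
    stop_usage("'clones' must be positive clone indices")
  }
  structure(list(n_spiked = as.integer(n_spiked), fold = fold,
                 placement = placement,
                 clones = if (is.null(clones)) NULL else as.integer(clones)),
            class = "spike_spec")
}

# True clone frequencies implied by the spec's abundance law.
abundance_probs <- function(spec) {
  k <- seq_len(spec$n_clones)
  w <- switch(spec$abundance_law$law,
              power_law = k^(-spec$abundance_law$exponent),
              log_series = spec$abundance_law$theta^k / k)
  w / sum(w)
}

.clone_ids <- function(idx, prefix = "C") sprintf("%s%06d", prefix, idx)

#' Simulate one repertoire sample
#'
#' Draws true clone frequencies from the spec's abundance law, then one
#' multinomial read sample of size \code{read_depth}; clones receiving
#' zero reads are dropped (they are unobserved), so the sample's
#' richness is the number of observed clones while its read depth is
#' exactly the multinomial total.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param sample_id,subject,timepoint,compartment metadata for the
#'   generated sample.
#' @return A \code{\link{tcr_repertoire}}.
#' @examples
#' spec <- simulation_spec(n_clones = 500, read_depth = 1e4, seed = 42)
#' rep <- simulate_repertoire(spec)
#' summary(rep)
#' @export
simulate_repertoire <- function(spec, sample_id = "sim",
                                subject = "simsubj",
                                timepoint = NA_character_,
                                compartment = NA_character_) {
  stopifnot(inherits(spec, "sim_spec"))
  probs <- abundance_probs(spec)
  counts <- with_seed(spec$seed,
                      as.numeric(stats::rmultinom(1, spec$read_depth, probs)))
  tcr_repertoire(.clone_ids(seq_along(counts)), counts,
                 subject = subject, timepoint = timepoint,
                 compartment = compartment, sample_id = sample_id)
}

#' Simulate a time course of repertoires for one subject
#'
#' A shared clone pool of size \code{shared_fraction * n_clones}
#' (selected at random under the spec's seed) persists across all time
#' points with unchanged true frequencies; the remaining abundance-law
#' slots are occupied by fresh clones at every time point, emulating the
#' turnover of transient clones. When a \code{\link{spike_spec}} is set,
#' the spiked clones' true frequencies are multiplied by its fold at
#' every post-baseline time point (then renormalized), emulating a
#' treatment-induced expansion; spiked clones are drawn from the shared
#' pool so they exist at baseline.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param n_timepoints number of serial samples (>= 2).
#' @param subject subject label for all generated samples.
#' @return List of \code{\link{tcr_repertoire}} objects with timepoint
#'   labels \code{T1..Tn}; the spiked clone identifiers (if any) are
#'   attached as attribute \code{"spiked"}.
#' @export
simulate_timecourse <- function(spec, n_timepoints = 2,
                                subject = "simsubj") {
  stopifnot(inherits(spec, "sim_spec"))
  assert_scalar_number(n_timepoints, "n_timepoints", lower = 2)
  probs <- abundance_probs(spec)
  n <- spec$n_clones
  n_shared <- round(spec$shared_fraction * n)
  if (spec$shared_fraction > 0 && n_shared < 1) {
    warning("shared_fraction * n_clones < 1; no shared clones generated")
    n_shared <- 0L
  }
  out <- with_seed(spec$seed, {
    shared_idx <- sort(sample.int(n, n_shared))
    spike_idx <- integer(0)
    if (!is.null(spec$spike)) {
      sp <- spec$spike
      pool <- if (!is.null(sp$clones)) {
        intersect(sp$clones, shared_idx)
      } else if (sp$placement == "top_quartile") {
        shared_idx[shared_idx <= ceiling(n / 4)]
      } else {
        shared_idx
      }
      if (length(pool) < sp$n_spiked) {
        stop_usage("spike placement pool has only %d clone(s) for %d spikes",
                   length(pool), sp$n_spiked)
      }
      spike_idx <- sort(sample(pool, sp$n_spiked))
    }
    samples <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      ids <- .clone_ids(seq_len(n))
      fresh <- setdiff(seq_len(n), shared_idx)
      ids[fresh] <- sprintf("T%d_%s", t, ids[fresh])
      p <- probs
      if (t > 1 && length(spike_idx)) {
        p[spike_idx] <- p[spike_idx] * spec$spike$fold
        p <- p / sum(p)
      }
      counts <- as.numeric(stats::rmultinom(1, spec$read_depth, p))
      samples[[t]] <- tcr_repertoire(
        ids, counts, subject = subject, timepoint = paste0("T", t),
        sample_id = paste0(subject, ".T", t))
    }
    attr(samples, "spiked") <- .clone_ids(spike_idx)
    names(samples) <- paste0("T", seq_len(n_timepoints))
    samples
  })
  out
}

#' Simulate an exchangeable null sample pair
#'
#' Two independent multinomial draws from one true frequency vector:
#' the exchangeable null used to calibrate the differential test (no
#' clone truly changes; both columns differ only by sampling noise).
#' Rows with zero total are dropped; both column sums equal the read
#' depth.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return A 2-column integer count matrix with columns \code{A},
#'   \code{B}.
#' @export
simulate_null_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  probs <- abundance_probs(spec)
  mat <- with_seed(spec$seed, {
    cbind(A = as.numeric(stats::rmultinom(1, spec$read_depth, probs)),
          B = as.numeric(stats::rmultinom(1, spec$read_depth, probs)))
  })
  rownames(mat) <- .clone_ids(seq_len(nrow(mat)))
  mat[rowSums(mat) > 0, , drop = FALSE]
}
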