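---
title: "Diversity, dynamics and differential testing of TCR repertoires"
author: "tcrdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, dynamics and differential testing of TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdyn)
```

## The data model

Bulk TCR-beta sequencing of a blood or tissue sample yields a table of
unique clonotypes — CDR3 sequences treated as clone identities — with a
read/template count $f_i$ each. `tcrdyn` works entirely on such tables.
A `tcr_repertoire` carries the counts, the derived frequencies
$p_i = f_i / F$ (where $F = \sum_i f_i$ is the read depth), the richness
$n$, and subject / time point / compartment metadata. Clonotypes are
keyed on the nucleotide CDR3 when available, because distinct
rearrangements can encode the same amino-acid sequence; amino-acid
keying is available where only that column exists. Zero-count rows are
dropped at load: every model in the package describes *observed*
clonotypes.

Real clonotype tables are heavily skewed towards rare clonotypes — a
large fraction of observed clones carry one or two reads. That single
fact drives most design choices below: it is why a count-threshold
robustness sweep exists, why size-factor estimation is restricted to
better-covered clones, and why the simulator defaults to a steep
rank–frequency law.

## Per-sample diversity

All entropies use the natural logarithm. For frequencies $p_1..p_n$:

* Renyi entropy $H_a = \frac{1}{1-a} \log \sum_i p_i^a$, with the
  analytic limits $H_1 = H$ (Shannon) and $H_\infty = -\log \max_i p_i$
  taken explicitly rather than by numerical continuation, so no
  tolerance ambiguity exists at the special orders.
* Hill numbers $N_a = e^{H_a}$, the effective clone counts, with
  $N_0 = n$, $N_1 = e^H$, $N_2 = D_2$ (inverse Simpson),
  $N_\infty = 1/\max p_i$. A sample is unambiguously more diverse than
  another only when its whole Hill profile is higher.
* Gini–Simpson $D_1 = 1 - \sum p_i^2$ and inverse Simpson
  $D_2 = 1/\sum p_i^2$.
* Pielou evenness $J = H / \log n$ and clonality $1 - J$: 0 for a
  perfectly even repertoire, 1 for a monoclonal one. At $n = 1$ the
  ratio is 0/0; clonality is defined as 1 there, the limit of a
  maximally restricted repertoire, and evenness as its complement.
* Geometric CV of $\log_{10} p_i$: with $S$ the sample standard
  deviation ($n-1$ denominator, matching the default in mainstream
  statistical software), the canonical Kirkwood form is
  $e^{S \ln 10} - 1$, which is zero at zero dispersion as a coefficient
  of variation must be. A variant circulating in the repertoire
  literature, $\exp(S \times 10 \times \ln 10 - 1)$, is provided behind
  `mode = "as_printed"`; note it equals $e^{-1}$ at zero dispersion, so
  it is not a CV in the strict sense, and the extra factor of 10 has no
  derivation we know of. Neither form is asserted "correct"; the
  canonical form is the default.

`threshold_sweep()` refilters the sample at increasing minimum counts
(default 2, 5, 10, 15, 20, 25, 30 — the range of cutoffs in routine
use), recomputing frequencies over the retained clones at each step.
Richness collapses by construction as the singleton tail is removed;
clonality moves comparatively little because it is normalized by
$\log n$ and invariant to uniform count scaling. The sweep is the
package's robustness check: indices that move little across thresholds
are safe endpoints for study designs where the preprocessing cutoff is
not fully under the analyst's control.

## Between-sample dynamics

Binary similarity works on presence/absence within a *declared
universe* — typically all samples of one subject. For a pair,
$n_1, n_2$ count clones present in each sample, $n_{12}$ in both, and
$d_{12}$ counts clones absent from both but present elsewhere in the
universe. The Baroni-Urbani & Buser index
$$BUB = \frac{n_{12} + \sqrt{n_{12} d_{12}}}{n_1 + n_2 - n_{12} +
\sqrt{n_{12} d_{12}}}$$
credits those negative matches, which makes the three pairwise values
over three serial samples comparable; with a pair-only universe
($d_{12} = 0$) it reduces exactly to Jaccard
$n_{12}/(n_1 + n_2 - n_{12})$. The correlation-like $BUB_2$ variant
spans $[-1, 1]$.

The Morisita overlap (Morisita–Horn form)
$$C_D = \frac{2\sum_i f_{ij} f_{ik}}
{\bigl(\sum_i f_{ij}^2/F_j^2 + \sum_i f_{ik}^2/F_k^2\bigr) F_j F_k}$$
is abundance-weighted: 0 for disjoint repertoires, 1 for identical
frequency profiles, invariant to proportional rescaling of either
sample. Sums run over the union of clonotypes; absent clones contribute
zero terms, so the universe question does not arise.

The intraclass correlation treats the common clones (present in every
compared sample) as subjects and the samples as repeated measurements
of $z_{ij} = \log_{10} p_{ij}$, returning the one-way random-effects
single-rater form
$$ICC(1,1) = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W},$$
equivalently $S_a^2/(S_a^2 + S_e^2)$ with $S_a^2 = (MS_B - MS_W)/k$ and
$S_e^2 = MS_W$. Restricting to common clones is deliberate: clones
absent from some samples would otherwise dominate the measure through
their imputed values. A union scope with half-count imputation
($0.5/F_j$) is available in `log_frequency_matrix()` but off by
default. We note the modelling convention is the one consistent with
standard ICC routines (subjects in rows); a model that assigned the
random effect to samples instead would measure the between-sample
variance fraction — the opposite of concordance — and cannot be
simultaneously honoured.

Per-clonotype fold changes $FC_i = \log_2(p_{ik}/p_{ij})$ are computed
over the overlap clones, or over the union with the absent side imputed
at half a count ($0.5/F$), which preserves the direction of change
without infinities; the imputation constant is a visible parameter.
Binning uses a symmetric cutoff $c$: decrease at $FC \le -c$, increase
at $FC \ge +c$, unchanged strictly between — boundaries inclusive on
the outer bins, so the three bins partition every scored clone. With
$c = 2$ the bins are frequency ratios below 1/4, within [1/4, 4], and
above 4. When the pair spans biological compartments (blood vs tissue),
`compartment_adjusted_c()` rescales the cutoff by
$\sum_i \log_2 p_{ik} / \sum_i \log_2 p_{ij}$ over the $m$ common
clones, exactly as stated, absorbing systematic compositional offsets
between compartments; both sums are negative for valid frequencies, so
the adjusted cutoff stays positive.

## Differential clonotype abundance without replicates

Clinical repertoire series rarely carry biological replicates: each
subject contributes one sample per time point. The test therefore
follows the no-replicate negative-binomial approach, with two
repertoire-specific modifications.

**Normalization.** Median-of-ratios size factors are estimated only on
clonotypes with at least 5 counts in some sample *and* nonzero counts
in all samples (the row geometric mean must exist). Low-count clones
are too noisy to inform normalization, but clones excluded here are
still tested. Factors are reported unscaled; only their ratios matter.

**Dispersion.** For a sample pair the two columns are treated as blind
replicates: per clonotype, the method-of-moments raw dispersion
$(\widehat{var}(q_i) - \bar q_i \overline{1/s}) / \bar q_i^2$ (floored
at 0) subtracts the expected shot noise from the empirical variance of
the normalized counts $q_{ij} = f_{ij}/s_j$. This deliberately absorbs
the normal week-to-week drift of the repertoire into the null model —
the substitute for replicates. The parametric family
$\alpha(\mu) = a_0 + a_1/\mu$ is fitted by least squares on $1/\mu$
with non-negativity clipping, one curve per pair, and curves are
combined by the element-wise median of the coefficients
(order-independent, robust to one aberrant pair; per-pair coefficients
are kept as provenance). Evaluation is floored at $10^{-8}$ — far
below any biologically meaningful dispersion — purely so the NB law
stays defined where the fit returns zero.

**Test.** For a clonotype with counts $(k_A, k_B)$ and size factors
$(s_A, s_B)$, the common concentration is
$\hat q = (k_A/s_A + k_B/s_B)/2$, the per-sample NB means are
$\mu_X = s_X \hat q$ with variance $\mu_X + \alpha(\hat q)\mu_X^2$, and
conditioning on $K = k_A + k_B$ gives the two-sided exact p-value by
probability-mass ordering over all splits of $K$. Splits are enumerated
exactly; above a cap (default $10^4$) the sum is accumulated in bounded
chunks, which is numerically identical. In the $\alpha \to 0$,
equal-factor limit the test collapses to the exact binomial$(K, 1/2)$
test, which the suite verifies to $10^{-9}$. Ties in the mass ordering
use the same relative tolerance ($1 + 10^{-7}$) as R's exact tests.
Reported log2 fold changes use normalized counts with a 0.5
pseudo-count on zero sides — reporting only, never inside the p-value.
Benjamini–Hochberg adjustment is applied within each pair's family of
tested clones (every clonotype with a nonzero pair total), and the
significant set is `fdr < 0.05` by default.

`tissue_presence_summary()` closes the loop for
blood-to-tissue questions: it flags which significantly changed blood
clones appear in a tissue sample, and compares their $\log_{10}$ tissue
counts against the mean over all tissue clones with a two-sided
one-sample t-test (skipped, with `NA`, when fewer than two testable
clones exist).

## Rank-abundance curves and intersections

`rank_abundance()` orders clones by descending count (ties broken
lexicographically by identifier, for fully deterministic output) and
plots $\log_{10}$ count against rank. Two curves are compared at
integer ranks as step functions — no interpolation, since counts are
integers and any interpolation rule would be an invention. The
intersection is the smallest rank where the count difference changes
sign relative to rank 1 (a tie at rank 1 is an immediate
intersection), and the headline `crossing_count` is read from the
curve that was higher at rank 1; both curves' counts are reported so
the other convention is also available. Because the curves typically
separate only in the low-count tail, the crossing count is a natural
candidate for a count-filter cutoff.

## The synthetic generator

`simulate_repertoire()` draws true clone frequencies from a
rank–frequency law and then a single multinomial read sample, so the
read depth is an exact invariant. Multinomial (fixed-total) sampling is
used rather than per-clone Poisson because real clonotype tables report
a fixed template total. The default law is a rank power law with
exponent 2 over 5,000 clones at depth $10^5$, which reproduces the
singleton-heavy shape (singleton fraction above 0.3) without fitting
any real dataset; a Fisher log-series is available. A flatter Zipf law
(exponent 1) is appropriate when a scenario needs many clones of
intermediate abundance.

`simulate_timecourse()` keeps a seeded random pool of
`shared_fraction` of the clones fixed across time points and replaces
the rest with fresh identities each time, emulating transient-clone
turnover; the default `shared_fraction = 0.8` reflects the
within-subject persistence typical of serial blood draws over a few
weeks. A `spike_spec` multiplies chosen clones' true frequencies by a
fold at post-baseline time points (renormalizing afterwards — so the
realized fold of a spiked clone is `fold` divided by the
renormalization constant, and every unspiked clone shifts down by that
same constant; the suite accounts for this). Spiked clones can be
placed in the top quartile, uniformly over the shared pool, or at
explicit abundance ranks when a scenario requires a guaranteed
baseline count. `simulate_null_pair()` draws two independent samples
from one frequency vector: the exchangeable null for calibration.

All generators restore the caller's RNG state and are bit-reproducible
under a fixed seed.

What the generator does *not* emulate: PCR amplification bias,
sequencing error producing spurious rare clonotypes, V/D/J usage
structure, and clone-size autocorrelation between time points beyond
all-or-nothing sharing. Passing simulation-based tests therefore
demonstrates the statistical machinery on clean multinomial data, not
robustness to those artifacts; on real data the low-count tail is
noisier than multinomial, which is precisely why the threshold sweep
and the ≥5-count normalization filter exist.

## Problem sizes and numerical choices

The simulation-based checks run at what we consider desk scale: null
calibration over 200 generated sample pairs (5,000 clones, depth
$10^5$ each), spike-in recovery on one pair with 50 spiked clones, and
index property checks over 500–1,000 random vectors or matrices. These
sizes give Monte-Carlo standard errors well below the margins being
asserted while keeping the whole suite around a minute on a laptop
core.

Notable degenerate-input rules, chosen for determinism: monoclonal
samples have clonality 1 and evenness 0; a count filter that empties a
sample is an error from `filter_by_count()` but a flagged-undefined
profile inside `threshold_sweep()`; identical columns give ICC exactly
1 (including the all-constant matrix); an empty overlap yields an
empty, flagged fold-change set; and the degenerate all-equal
fold-change density is emitted as a discrete unit mass rather than a
kernel of zero bandwidth.

## Known limitations

* The differential test's dispersion is estimated from the very
  contrast being tested (blind pairs); truly replicated designs should
  use replicate-based dispersion estimation instead, which is out of
  scope here.
* Group-level inference across subjects (repeated-measures ANOVA,
  mixed models on the index tables) is intentionally not included; the
  package's tidy outputs are designed to feed such analyses.
* Binary similarity values depend on the declared universe; comparing
  BUB values computed against different universes is not meaningful.
* No rarefaction or coverage-based richness correction is provided:
  observed richness is depth-dependent, which is exactly why clonality
  is the recommended primary endpoint.
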