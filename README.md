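# tcrdyn

Analysis of T-cell receptor (TCR) repertoires sampled over time and
across biological compartments, for immunologists and biostatisticians
working with clonotype count tables from bulk AIRR-seq (e.g. ImmunoSEQ
exports or AIRR Rearrangement TSVs). The package answers three
questions about a subject's repertoire:

1. **Diversity** — how restricted is the repertoire at one time point?
   Renyi entropies $H_a = \frac{1}{1-a}\log\sum_i p_i^a$ and Hill
   numbers $N_a = e^{H_a}$ (with $N_0 = n$, $N_1 = e^H$, $N_2$ the
   inverse Simpson, $N_\infty = 1/\max p_i$), Shannon, Gini–Simpson,
   Pielou evenness, clonality $1 - H/\log n$, and the geometric CV of
   $\log_{10} p_i$ — plus a count-threshold sweep showing which indices
   are robust to filtering the noisy low-count tail.
2. **Dynamics** — how much did the repertoire change between samples?
   Jaccard and Baroni-Urbani & Buser binary similarity within a
   declared clone universe, the Morisita overlap
   $C_D \in [0, 1]$, relative clonality, a one-way random-effects
   intraclass correlation on $\log_{10}$ frequencies of the common
   clones, and log2 fold-change binning (decrease / unchanged /
   increase at a cutoff $c$, with a compartment adjustment for
   blood-vs-tissue comparisons).
3. **Differential testing** — *which* clonotypes changed? A
   no-replicate negative-binomial exact test per clonotype:
   median-of-ratios size factors estimated on clonotypes with ≥ 5
   counts in some sample, a dispersion–mean curve
   $\alpha(\mu) = a_0 + a_1/\mu$ fitted blind on sample pairs and
   combined as the median across pairs, an exact conditioned two-sided
   test on each clone's count split, and Benjamini–Hochberg control at
   FDR < 0.05 — followed by a tissue-presence summary of the
   significant clones.

Rank-abundance curve utilities (with intersection-point detection, a
principled way to pick a count cutoff), a seeded synthetic-repertoire
generator used by the test suite, and a command-line interface round
out the toolkit.

## Worked example

Simulate a three-time-point study for one subject (5 × 10⁴ reads,
2,000 true clones, 80% of clones persisting between time points), then
run the three analysis layers:

```r
library(tcrdyn)

spec <- simulation_spec(n_clones = 2000, read_depth = 5e4,
                        shared_fraction = 0.8, seed = 42)
tc <- simulate_timecourse(spec, n_timepoints = 3)

diversity_profile(tc$T1)
#> Diversity profile of 'simsubj.T1' (min count 1)
#>   n_unique 272, read depth 50,000
#>   Shannon 1.6211 | clonality 0.7108 | evenness 0.2892
#>   Gini-Simpson 0.5988 | inverse Simpson 2.4927 | GCV (canonical) 5.0712
#>   Hill numbers:
#>        0        1        2      Inf
#> 272.0000   5.0588   2.4927   1.6423
```

272 unique clones were observed; the effective number of clones drops
from 272 (richness) to 5.06 (Shannon scale) to 2.49 (Simpson scale),
and clonality 0.71 says the repertoire is strongly dominated by its
top clones — as the steep abundance law dictates.

```r
pairwise_dynamics(tc$T1, tc$T2, universe = tc)
#>     sample_1   sample_2   jaccard       bub       bub2  morisita
#> 1 simsubj.T1 simsubj.T2 0.3373494 0.5062712 0.01254235 0.9996026
#>   relative_clonality       icc
#> 1           1.001759 0.9578908
```

Only a third of the pooled clones appear at both time points (the
transient low-count tail turns over), yet the Morisita overlap of
0.9996 and ICC of 0.96 show the *abundant* clones barely moved —
a textbook stable repertoire.

```r
mat <- to_count_matrix(tc)
run_difftest(mat, pairs = list(c("simsubj.T1", "simsubj.T2")))
#> differential clonotype abundance (per_pair scope, FDR < 0.05)
#>   simsubj.T1 vs simsubj.T2: 415 tested, 2 significant (1 increase, 1 decrease)

find_intersection(rank_abundance(tc$T1), rank_abundance(tc$T2))
#> curves simsubj.T1 / simsubj.T2 intersect at rank 2 (counts 7619 / 7531); crossing count 7531
```

The same pipeline is available from the shell via the installed script
(`system.file("cli", "tcrdyn", package = "tcrdyn")`): `simulate`,
`diversity`, `dynamics`, `difftest`, `curves` and `robustness`
subcommands read a sample manifest and write tidy TSVs plus a JSON run
report.

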