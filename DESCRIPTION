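Package: tcrdyn
Title: Diversity, Dynamics and Differential Testing of T-Cell Receptor
    Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of T-cell receptor (TCR) clonotype count tables from
    AIRR-seq experiments sampled at serial time points and/or in multiple
    biological compartments. Provides per-sample diversity indices (Renyi
    entropies and Hill numbers, Shannon, Gini-Simpson, inverse Simpson,
    Pielou evenness, clonality, geometric coefficient of variation) with a
    count-threshold robustness sweep; between-sample dynamics measures
    (Jaccard and Baroni-Urbani & Buser binary similarity, Morisita overlap,
    relative clonality, one-way random-effects intraclass correlation on
    log clone frequencies, fold-change binning with compartment
    adjustment); a no-replicate negative-binomial exact test for
    per-clonotype differential abundance with median-of-ratios
    normalization and a median-of-curves dispersion model; rank-abundance
    curves with intersection-point detection; a seeded synthetic-repertoire
    generator; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
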