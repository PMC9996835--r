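Package: eukbench
Title: Ensemble Identification and Benchmarking of Eukaryotic Sequences in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recovering eukaryotes from metagenome assemblies and for
    benchmarking the tools that do so. Implements a hybrid ensemble classifier for
    contigs (reference-based calls first, majority vote over k-mer-based tools as
    fallback, with separate minimum-length thresholds), a mock-metagenome simulator
    (lognormal genome abundances under an imposed eukaryote:prokaryote base-pair
    ratio, fixed-length test contigs, length-stratified synthetic classifier calls),
    an imbalance-aware benchmarking protocol (ratio-constrained subsampling repeated
    many times, scored by Matthews correlation coefficient, precision and recall),
    bin-quality scoring against a gold standard (purity, completeness, F1,
    base-pair-weighted adjusted Rand index) under alternative assembly-filtering
    strategies, and community-level statistics for environmental surveys:
    breadth-of-coverage presence calls, per-superkingdom base-pair fractions,
    k-means sample clustering, and hypergeometric presence-absence co-occurrence
    networks with Leiden modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
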