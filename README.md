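# eukbench

Microbial eukaryotes — fungi, amoebae, ciliates, algae — are a small but
consequential component of many engineered and environmental microbiomes,
typically contributing only a few percent of the base pairs in a shotgun
metagenome. Recovering them from assemblies is a two-stage problem:
deciding, contig by contig, what is eukaryotic, and then judging how well
binning reassembles the eukaryotic genomes. Both stages are easy to get
wrong under severe class imbalance, where accuracy-style metrics are
uninformative.

`eukbench` is an R toolkit for people who build or evaluate such
workflows. It provides:

- **Hybrid ensemble classification.** A contig's label comes from a
  reference-based classifier whenever one annotated it (and the contig is
  at least 1 kbp); otherwise from a strict majority vote over k-mer-based
  classifiers (ties excluded), applied only to contigs of at least 3 kbp.
  Votes of "unclassified" are discarded before counting, so two
  disagreeing informative votes are a tie and yield no label.
- **Imbalance-aware benchmarking.** Predictions are scored after randomly
  subsampling the benchmark set to a eukaryote:prokaryote base-pair ratio
  of 0.05 (typical of real surveys), repeated 100 times; the Matthews
  correlation coefficient

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

  precision and recall are reported as mean ± sd over repeats.
- **A mock-metagenome simulator.** Genome catalogs, per-sample
  compositions with lognormal(μ = 1, σ = 2) abundances under an exactly
  imposed eukaryote:prokaryote bp ratio, fixed-length test contigs (1, 3,
  5 kbp; 100 per genome), classifier calls from length-stratified error
  profiles, and coverage tables with controllable breadth.
- **Binning evaluation.** FULL / EUK-only / OTHER-rem input strategies,
  percentage of eukaryotic bp binned, bp-weighted purity, completeness
  and F1 of eukaryotic bins (most-complete-bin and all-bins variants),
  and a bp-weighted adjusted Rand index against the gold standard.
- **Community statistics.** Presence calls at ≥ 25% breadth of coverage,
  per-superkingdom bp fractions, k-means clustering of samples on
  sequencing coverage and logit eukaryotic fraction, and hypergeometric
  presence–absence co-occurrence networks partitioned into Leiden
  modules.

Everything takes and returns tibbles, so stages chain with the pipe;
results carry `tidy()`, `glance()` and `autoplot()` methods.

## A worked example

Simulate a small benchmark, classify it with the hybrid ensemble, and
score it under the imbalanced protocol:

```r
library(eukbench)

catalog <- simulate_genome_catalog(n_euk = 8, n_prok = 40,
                                   euk_mean_bp = 5e5, prok_mean_bp = 2e5,
                                   seed = 1)
manifest <- extract_test_contigs(catalog, n_per_genome = 25, seed = 2)
calls    <- simulate_calls(manifest, default_error_profiles(), seed = 3)
final    <- classify_assembly(manifest, calls, ensemble_config())

evaluate_classifier(final, manifest, ratio = 0.05, n_repeats = 100, seed = 4)
#> Eukaryote classification benchmark (100 subsampling repeats, bp ratio 0.05, unclassified as_negative)
#> # A tibble: 3 × 4
#>   metric     mean      sd n_repeats
#>   <chr>     <dbl>   <dbl>     <dbl>
#> 1 mcc       0.788 0.0141        100
#> 2 precision 0.770 0.00663       100
#> 3 recall    0.829 0.0247        100
```

The mean MCC of 0.79 says the ensemble's agreement with truth is strong
even though eukaryotes are only ~5% of the base pairs in each evaluation
subsample; the sd across the 100 ratio-constrained subsamples shows how
much the score depends on which prokaryotic contigs happen to be drawn.
Precision (0.77) and recall (0.83) decompose the errors: the ensemble
leaves short contigs unlabelled (counted as negatives here), which costs
recall at 1 kbp where only the abstention-prone reference tool may act.

Binning evaluation and community statistics work the same way:

```r
bq <- evaluate_binning(bins, gold)   # bins, gold: contig→bin / contig→genome tables
glance(bq)                            # % euk bp binned, ARI, mean purity/completeness/F1

presence <- presence_calls(coverage)          # breadth >= 0.25
edges    <- cooccurrence_edges(presence)      # hypergeometric, p < 0.05
modules  <- detect_modules(edges, seed = 1)   # Leiden; reported if > 10 taxa
```

A command-line front end over the same functions ships in
`inst/cli/eukbench.R` (subcommands `convert`, `classify`, `simulate`,
`bench-classify`, `bench-binning`, `community`).

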