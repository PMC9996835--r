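---
title: "Models and design choices behind eukbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind eukbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eukbench)
```

`eukbench` evaluates and applies workflows that recover microbial
eukaryotes from shotgun metagenome assemblies. This vignette explains the
models behind each stage, the parameters that matter, what the built-in
simulator does and does not emulate, and the choices we made where the
design was genuinely open.

## The hybrid ensemble classifier

Two families of contig classifiers behave very differently. K-mer-based
tools label essentially every contig from nucleotide composition alone,
with error rates that fall steeply with contig length. Reference-based
tools align predicted genes against databases: when they answer they are
nearly always right, but they abstain on a large fraction of contigs —
disproportionately eukaryotic ones, whose references are sparse.

The ensemble combines them asymmetrically:

1. If the contig is at least `min_len_ref_bp` (default 1000 bp) long and
   the reference tool produced any informative call, that call is final.
   This applies to *negative* reference calls too: the OTHER-rem binning
   strategy below depends on contigs being positively identified as
   non-eukaryotic, so a reference tool's "prokaryote" must be allowed to
   stand.
2. Otherwise, if the contig is at least `min_len_kmer_bp` (default
   3000 bp) long, a majority vote over the configured k-mer tools
   decides. Votes of "unclassified" are removed before counting and the
   winner must hold a strict majority; an exact tie yields no label. We
   deliberately implement no tie-break — no tool is senior — because the
   vote's value lies in demanding genuine agreement.
3. Contigs below the reference length threshold are never labelled.

The two length defaults reflect where each family becomes trustworthy:
reference calls are already reliable at 1 kbp, while composition signals
need roughly 3 kbp of sequence. Both are configurable through
`ensemble_config()`. The default k-mer trio omits the oldest
composition classifier in favour of three complementary, more recent
ones; the reference slot defaults to a protein-alignment classifier.

A consequence worth knowing: under the vote semantics, two informative
votes that disagree after one abstention produce *no* label, so a
three-tool ensemble abstains more often than its members. The benefit is
precision under imbalance; the cost is recall on short or ambiguous
contigs. The benchmark protocol below makes exactly this trade-off
visible.

## Benchmarking under class imbalance

Environmental metagenomes typically carry eukaryote:prokaryote base-pair
ratios near 0.05. A classifier evaluated on a balanced test set will look
far better than it behaves in production, and accuracy is uninformative
when 95% of the bp are negative. The protocol therefore:

- subsamples the benchmark set to the target bp ratio (default 0.05) by
  randomly discarding contigs of the over-represented class, one at a
  time, until the realized ratio first crosses the target (so the
  realized ratio is within one contig's bp of the target — checked as a
  property);
- scores the Matthews correlation coefficient, precision and recall with
  the eukaryote as the positive class; any zero denominator defines the
  value as 0 and sets a `degenerate` attribute rather than returning NaN;
- repeats the subsampling 100 times (configurable) and reports mean and
  sd per metric.

Unclassified predictions are counted as negative calls by default
(`unclassified_mode = "as_negative"`): this is the end-to-end view, where
an abstention on a true eukaryote is a miss. The alternative
(`"exclude"`) drops unlabelled contigs before counting, which is the view
under which abstention-heavy reference tools report near-perfect scores;
offering both makes that often-confusing discrepancy explicit.

## The simulator and what it stands in for

The generator replaces genome databases, read simulation and the external
classifiers, so every stage can be exercised from code:

- **Genome catalog** (`simulate_genome_catalog()`): 33 eukaryotic and 216
  prokaryotic genomes by default, with lognormal genome sizes (medians
  30 Mbp and 4 Mbp) split into contigs by a broken-stick rule. These
  scales are ordinary for assembled microbial eukaryotes and prokaryotes;
  only the relative magnitudes matter downstream.
- **Composition** (`sample_composition()`): per-genome abundances are
  drawn lognormal with μ = 1, σ = 2 *on the log scale* (the conventional
  parameterization; the common read-simulation pipelines use the same
  convention), and bp share is abundance × genome length. All eukaryotic
  abundances are then rescaled by one common factor so the
  eukaryote:prokaryote bp ratio equals 0.05 *exactly in every sample* —
  not merely in expectation — leaving the within-superkingdom structure
  intact. Enforcing the ratio exactly is a choice: it makes the imbalance
  a controlled experimental condition rather than a random one.
- **Test contigs** (`extract_test_contigs()`): 100 fragments per genome
  per target length (1, 3, 5 kbp), cut at uniform random positions from
  source contigs long enough to hold them. We read "100 fragments" as per
  genome and per length — the alternative (100 in total) would make
  per-tool performance estimates too unstable to compare. Fragments may
  overlap: 100 non-overlapping 5 kbp fragments simply do not fit in small
  contigs, and overlap is harmless for classifier evaluation.
- **Classifier calls** (`simulate_calls()`): per length bin, a tool has a
  sensitivity, a specificity and an abstention rate. The shipped default
  profiles encode the qualitative behaviours described above — k-mer
  tools improving with length and rarely abstaining; a reference tool
  that is ~98% accurate conditional on answering but abstains on 38–45%
  of contigs.
- **Coverage** (`simulate_coverage()`): a contig's expected depth is
  proportional to its genome's abundance, with gamma noise; breadth
  follows the Poisson-coverage relation 1 − e^(−depth). This produces the
  patchy low-breadth profiles that the 25% presence rule is designed to
  reject.

What the simulator does **not** emulate: sequencing error, chimeric and
fragmented assembly, inter-genome compositional similarity (errors are
independent across tools and contigs given the profile), strain-level
variation, and database contents. Passing benchmarks on simulated calls
therefore validates the *combination and evaluation logic*, not any
claim about how real classifiers behave on real contigs — for that, real
call tables are parsed in via the dialect readers.

## Binning evaluation

Against a gold contig→genome map, three views of bin quality, all
bp-weighted (each contig counts its length; contig-count weighting is
available as an option):

- **% eukaryotic bp binned** — recovery regardless of arrangement.
- **Purity / completeness / F1**, restricted to *eukaryotic bins* (bins
  whose bp are majority-eukaryotic, strictly). Purity is the bp share of
  the bin's majority genome; completeness of a genome in a bin is the
  genome's bp in the bin over the genome's bp *in the filtered assembly*
  — fragments excluded by the binner's length cutoff were never
  candidates, so they do not enter the denominator. The
  `most_complete_bin` variant reports one F1 per eukaryotic genome (its
  most complete bin's completeness with that bin's purity); `all_bins`
  scores every eukaryotic bin against its own majority genome. Summaries
  are unweighted means. The all-bins variant has no single canonical
  definition in the literature; ours is stated here precisely so results
  are interpretable.
- **Adjusted Rand index** on the genome×bin contingency table of binned
  bp, chance-corrected. Unbinned contigs are excluded — the index
  measures agreement on what was binned; including unbinned contigs as
  singletons would change the values substantially, so the exclusion is
  documented prominently. A single-cell table is flagged degenerate with
  value 1.

Input strategies mirror practice: `FULL` (everything above the length
cutoff), `EUK_only` (only eukaryote-labelled contigs) and `OTHER_rem`
(eukaryote-labelled plus unclassified, i.e. only positively
non-eukaryotic contigs removed). The cutoffs 1, 1.5 and 3 kbp correspond
to common binner minimums.

## Community statistics

- **Presence**: a contig is present in a sample when breadth of coverage
  is ≥ 0.25 (inclusive, per "at least 25%"). Depth alone is not used:
  spurious cross-sample mappings onto conserved regions produce high
  local depth but low breadth.
- **bp fractions**: per sample, each present contig contributes
  mean depth × length (≈ mapped bp) to its label's share; fractions sum
  to 1 per sample. Weighting by assembled length alone is available via
  `weight = "length"`.
- **Sample clustering**: k-means (k = 2 by default, since the analysis
  distinguishes exactly a eukaryote-poor and a eukaryote-rich regime) on
  z-scored Nonpareil coverage and logit eukaryotic fraction. Zero
  fractions get half the smallest nonzero fraction before the logit (a
  pseudocount choice the source analyses leave open; mirrored at 1). Only
  the fraction is logit-transformed — the coverage variable is already
  approximately scale-free — and the cluster with the lower mean
  eukaryotic fraction is always the one named "eukaryotic-deficient",
  independent of k-means' internal labelling.
- **Co-occurrence network**: for each taxon pair, the one-tailed
  hypergeometric enrichment p-value of their co-presence count over N
  samples; edges at p < 0.05. One-tailed co-presence only — mutual
  exclusion edges are out of scope. No multiple-testing correction by
  default, matching a plain per-edge threshold; a Benjamini–Hochberg
  option exists but changes the network and is off by default.
- **Modules**: Leiden modularity maximization (resolution 1, seeded) on
  the significant-edge graph. All modules are returned; the `reported`
  flag marks those with more than 10 taxa, the size convention for
  describing recurrent modules.

## Numerical conventions and degenerate inputs

- Zero denominators in MCC/precision/recall → value 0 plus a
  `degenerate` attribute (never NaN).
- Ratio subsampling stops at the first crossing of the target, so the
  inevitable discreteness error is bounded by one contig's bp.
- A bin map whose every contig is unbinned has no ARI; an assembly with
  no eukaryotic bp has no binned-fraction — both are flagged, not
  silently zeroed.
- Clustering with fewer distinct profiles than clusters warns and
  returns a degenerate single-cluster result.
- All stochastic functions take explicit seeds; identical seeds give
  identical outputs (the end-to-end test checks byte-identical JSON).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data
at sizes chosen to make Monte-Carlo checks sharp while staying quick on a
laptop: catalogs of ~10–50 genomes with 0.1–0.5 Mbp genomes for pipeline
tests, 10,000 contigs for vote-superiority and call-rate convergence
checks, 100 subsampling repeats (matching the protocol default), 1,000
samples for lognormal moment checks, and exhaustive enumeration wherever
the space is small (all 243 vote×length×reference cases; all
hypergeometric configurations up to 6 samples).

## Known limitations

- The ensemble's vocabulary is binary-plus-abstention; finer-grained
  non-eukaryote labels (prokaryote vs virus) must come from the inputs,
  as in the community stage's four-way fractions.
- The mapping from multi-class tool outputs to the vocabulary ships as
  editable per-dialect label maps; how one reference tool's lineages
  below superkingdom should collapse is not standardized, so that map in
  particular may need adjustment to local tool versions.
- Bin-quality averaging conventions differ across evaluation tools and
  versions; numbers here follow the definitions above and are not
  guaranteed to match any specific external evaluator's averages.
- The simulator's independence assumptions (between tools, between
  contigs) are favourable to majority voting; correlated tool errors on
  real data will shrink the ensemble's margin.
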