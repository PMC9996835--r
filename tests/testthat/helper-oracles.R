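# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately coded on different paths than the package
# (enumeration, tallying, pair counting, correlation identities).

norm_labels <- c("eukaryote", "noneukaryote", "unclassified")

# brute-force majority: tabulate informative votes, demand a unique max
oracle_majority <- function(votes) {
  v <- votes[votes != "unclassified"]
  if (length(v) == 0) return("unclassified")
  tab <- table(v)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) winners else "unclassified"
}

# brute-force hybrid rule, written straight from its definition
oracle_hybrid <- function(len, ref, votes, min_ref = 1000, min_kmer = 3000) {
  if (len >= min_ref && ref != "unclassified") return(ref)
  if (len >= min_kmer) return(oracle_majority(votes))
  "unclassified"
}

# MCC as the Pearson correlation of the reconstructed 0/1 vectors
oracle_mcc_cor <- function(TP, FP, TN, FN) {
  truth <- c(rep(1, TP), rep(0, FP), rep(0, TN), rep(1, FN))
  pred <- c(rep(1, TP), rep(1, FP), rep(0, TN), rep(0, FN))
  suppressWarnings(stats::cor(truth, pred))
}

# ARI by explicit pair counting over expanded (bp-weighted) units
oracle_ari_pairs <- function(binmap, goldmap, unit = 1) {
  j <- merge(binmap, goldmap, by = "contig_id")
  j <- j[!is.na(j$bin_id) & j$bin_id != "unbinned", ]
  reps <- j$length_bp / unit
  stopifnot(all(reps == round(reps)))
  g <- rep(j$source_genome_id, reps)
  b <- rep(j$bin_id, reps)
  n <- length(g)
  a <- d <- bb <- cc <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    sg <- g[i] == g[k]; sb <- b[i] == b[k]
    if (sg && sb) a <- a + 1
    else if (sg && !sb) bb <- bb + 1
    else if (!sg && sb) cc <- cc + 1
    else d <- d + 1
  }
  denom <- (a + bb) * (bb + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - bb * cc) / denom
}

# exact co-presence enrichment tail by enumerating all placements of B
oracle_hyper_enum <- function(set_a, k_b, n, x_obs) {
  hits <- 0; total <- 0
  for (cols in utils::combn(n, k_b, simplify = FALSE)) {
    total <- total + 1
    if (length(intersect(set_a, cols)) >= x_obs) hits <- hits + 1
  }
  hits / total
}

random_manifest <- function(n, seed, p_euk = 0.3,
                            lengths = c(500L, 1000L, 2000L, 3500L, 5000L)) {
  set.seed(seed)
  lab <- sample(c("eukaryote", "prokaryote", "virus"), n, replace = TRUE,
                prob = c(p_euk, 0.85 * (1 - p_euk), 0.15 * (1 - p_euk)))
  tibble::tibble(contig_id = sprintf("ctg%04d", seq_len(n)),
                 length_bp = sample(lengths, n, replace = TRUE),
                 true_label = lab,
                 source_genome_id = paste0("g_", lab))
}

random_calls <- function(manifest, tools, seed) {
  set.seed(seed)
  do.call(rbind, lapply(tools, function(tl) {
    lab <- sample(norm_labels, nrow(manifest), replace = TRUE)
    tibble::tibble(contig_id = manifest$contig_id, tool_id = tl,
                   raw_label = lab, norm_label = lab)
  }))
}

clique_edges <- function(n, prefix) {
  p <- t(utils::combn(sprintf("%s%02d", prefix, seq_len(n)), 2))
  tibble::tibble(taxon_a = p[, 1], taxon_b = p[, 2])
}

two_genome_catalog <- function() {
  tibble::tibble(
    genome_id = c("euk1", "prok1"),
    superkingdom = c("eukaryote", "prokaryote"),
    total_length_bp = c(1000000L, 2000000L),
    contig_lengths = list(1000000L, c(1500000L, 500000L)))
}

small_catalog <- function(seed = 11) {
  simulate_genome_catalog(n_euk = 3, n_prok = 8,
                          euk_mean_bp = 2e5, prok_mean_bp = 1e5, seed = seed)
}
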