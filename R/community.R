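# Community-level statistics for environmental metagenome surveys:
# breadth-of-coverage presence calls, per-superkingdom bp fractions,
# k-means clustering of samples by sequencing coverage and eukaryotic
# fraction, and hypergeometric presence-absence co-occurrence networks
# partitioned into Leiden modules.

#' Presence calls from breadth of coverage
#'
#' A contig (or 18S gene) is considered present in a sample when at least
#' a minimum fraction of its bases is covered by one or more mapped reads
#' (default 25%, inclusive). The breadth criterion suppresses spurious
#' presence calls arising from reads mapping onto short conserved regions
#' of co-assembled contigs.
#'
#' @param cov Long coverage table with `sample_id`, `contig_id`,
#'   `mean_depth`, `breadth` (fraction of bases covered, in `[0, 1]`).
#' @param breadth_min Inclusive presence threshold on breadth (default 0.25).
#' @param prune Drop contigs absent everywhere and samples with nothing
#'   present (default `TRUE`).
#' @return A wide logical tibble: one row per contig (`taxon_id` column),
#'   one column per sample.
#' @export
presence_calls <- function(cov, breadth_min = 0.25, prune = TRUE) {
  required <- c("sample_id", "contig_id", "breadth")
  missing <- setdiff(required, names(cov))
  if (length(missing) > 0) {
    abort(paste0("coverage table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(cov$breadth) || any(cov$breadth < 0 | cov$breadth > 1)) {
    abort("breadth must lie in [0, 1]")
  }
  wide <- cov |>
    mutate(present = .data$breadth >= breadth_min) |>
    select("contig_id", "sample_id", "present") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "present",
                       values_fill = FALSE) |>
    rename(taxon_id = "contig_id")
  if (prune && nrow(wide) > 0) {
    m <- as.matrix(wide[-1])
    wide <- wide[rowSums(m) > 0, c(TRUE, colSums(m) > 0), drop = FALSE]
  }
  wide
}

.presence_matrix <- function(presence) {
  if (is.matrix(presence)) {
    storage.mode(presence) <- "logical"
    return(presence)
  }
  if (!"taxon_id" %in% names(presence)) {
    abort("presence table needs a taxon_id column (see presence_calls())")
  }
  m <- as.matrix(presence[setdiff(names(presence), "taxon_id")])
  rownames(m) <- presence$taxon_id
  storage.mode(m) <- "logical"
  m
}

#' Per-sample base-pair fractions by superkingdom
#'
#' Estimates, from coverage over present contigs, the share of each
#' sample's mapped assembled base pairs attributable to eukaryotes,
#' prokaryotes, viruses and unclassified contigs. Each present contig
#' contributes `mean_depth * length_bp` (an approximation of its mapped
#' bp); set `weight = "length"` to weigh by assembled length alone.
#'
#' @param cov Coverage table with `sample_id`, `contig_id`, `mean_depth`,
#'   `breadth`, and `length_bp` (or supply `manifest`).
#' @param labels Table with `contig_id` and a label column (`label` or
#'   `final_label`) over `eukaryote`, `prokaryote`, `virus`,
#'   `noneukaryote`, `unclassified`; it must cover every contig in `cov`.
#' @param manifest Optional contig manifest supplying `length_bp` when the
#'   coverage table lacks it.
#' @param breadth_min Presence threshold handed to the same rule as
#'   [presence_calls()].
#' @param weight `"depth_length"` (default) or `"length"`.
#' @return A long tibble `sample_id`, `label`, `fraction`; fractions sum
#'   to 1 per sample. Samples with no present contig are dropped with a
#'   warning.
#' @export
bp_fractions <- function(cov, labels, manifest = NULL, breadth_min = 0.25,
                         weight = c("depth_length", "length")) {
  weight <- arg_match(weight)
  lab_col <- intersect(c("label", "final_label"), names(labels))[1]
  if (is.na(lab_col)) abort("labels need a 'label' or 'final_label' column")
  if (!"length_bp" %in% names(cov)) {
    if (is.null(manifest)) abort("supply length_bp in cov or pass a manifest")
    cov <- left_join(cov, select(validate_contig_manifest(manifest),
                                 "contig_id", "length_bp"), by = "contig_id")
  }
  lab <- labels[[lab_col]][match(cov$contig_id, labels$contig_id)]
  if (anyNA(lab)) abort("labels must cover every contig in the coverage table")
  ok <- c("eukaryote", "prokaryote", "virus", "noneukaryote", "unclassified")
  if (!all(lab %in% ok)) abort("unknown label in labels table")
  x <- cov |>
    mutate(label = lab,
           present = .data$breadth >= breadth_min,
           w = if (weight == "depth_length") {
             .data$mean_depth * as.numeric(.data$length_bp)
           } else {
             as.numeric(.data$length_bp)
           }) |>
    filter(.data$present)
  empty <- setdiff(unique(cov$sample_id), unique(x$sample_id))
  if (length(empty) > 0) {
    warn(sprintf("%d sample(s) with no present contig dropped (e.g. '%s')",
                 length(empty), empty[1]))
  }
  x |>
    group_by(.data$sample_id, .data$label) |>
    summarise(w = sum(.data$w), .groups = "drop_last") |>
    mutate(fraction = .data$w / sum(.data$w)) |>
    ungroup() |>
    select("sample_id", "label", "fraction")
}

#' Cluster samples by sequencing coverage and eukaryotic fraction
#'
#' Samples are clustered with k-means on two variables: the sample's
#' Nonpareil coverage (how completely its sequence diversity was sampled)
#' and the logit of its eukaryotic bp fraction. Zero fractions are
#' replaced by half the smallest nonzero fraction before the logit (and
#' fractions of one by the mirrored rule); both variables are then
#' z-scored. With `k = 2`, the cluster with the lower mean eukaryotic
#' fraction is named `eukaryotic-deficient` and the other
#' `eukaryotic-increasing`, regardless of k-means' internal ordering.
#'
#' @param samples Tibble with `sample_id`, `nonpareil_coverage` (in
#'   `[0, 1]`) and `euk_fraction` (in `[0, 1]`).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed for the k-means restarts.
#' @param n_init Number of random restarts (default 25).
#' @return A tibble `sample_id`, `cluster` (named as above for `k = 2`,
#'   `cluster_1`..`cluster_k` ordered by mean eukaryotic fraction
#'   otherwise), with the fitted k-means object in attribute `"kmeans"`.
#' @export
cluster_samples <- function(samples, k = 2L, seed = 1L, n_init = 25L) {
  required <- c("sample_id", "nonpareil_coverage", "euk_fraction")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("samples table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  f <- samples$euk_fraction
  if (anyNA(f) || any(f < 0 | f > 1)) abort("euk_fraction must lie in [0, 1]")
  if (nrow(samples) < k) abort("need at least k samples")
  nz <- f[f > 0]
  if (length(nz) == 0) abort("all eukaryotic fractions are zero")
  f[f == 0] <- min(nz) / 2
  cmpl <- 1 - f
  nzc <- cmpl[cmpl > 0]
  if (length(nzc) > 0) f[cmpl == 0] <- 1 - min(nzc) / 2
  z <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  X <- cbind(coverage = z(samples$nonpareil_coverage),
             logit_euk = z(log(f / (1 - f))))
  if (nrow(unique(X)) < k) {
    warn("fewer distinct sample profiles than clusters; degenerate clustering")
    out <- tibble(sample_id = samples$sample_id,
                  cluster = "eukaryotic-deficient")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = n_init)
  mean_frac <- tapply(samples$euk_fraction, km$cluster, mean)
  ord <- order(mean_frac)  # ascending eukaryotic fraction
  nm <- if (k == 2) c("eukaryotic-deficient", "eukaryotic-increasing")
        else sprintf("cluster_%d", seq_len(k))
  name_of <- setNames(nm, names(mean_frac)[ord])
  out <- tibble(sample_id = samples$sample_id,
                cluster = unname(name_of[as.character(km$cluster)]))
  attr(out, "kmeans") <- km
  attr(out, "degenerate") <- FALSE
  out
}

#' Hypergeometric co-occurrence edges from a presence-absence matrix
#'
#' For every pair of taxa with prevalences K_A and K_B over N samples and
#' co-presence count x, tests co-presence enrichment under the
#' hypergeometric null (sampling K_B of N samples without replacement):
#' `p = P(X >= x)`. Edges with `p < alpha` are flagged significant.
#' One-tailed enrichment only — mutual-exclusion edges are not produced.
#' No multiple-testing correction is applied by default, matching a plain
#' per-edge significance threshold; `adjust = "BH"` adds
#' Benjamini-Hochberg adjusted p-values and flags on those instead.
#'
#' @param presence A wide presence tibble from [presence_calls()] or a
#'   logical matrix (taxa in rows, samples in columns).
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of unordered taxon pairs (no self-pairs):
#'   `taxon_a`, `taxon_b`, `prevalence_a`, `prevalence_b`, `co_count`,
#'   `p_value` (and `p_adjusted`), `significant`.
#' @export
cooccurrence_edges <- function(presence, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- arg_match(adjust)
  m <- .presence_matrix(presence)
  N <- ncol(m)
  if (N < 2) abort("need at least 2 samples")
  n_taxa <- nrow(m)
  if (n_taxa < 2) {
    return(tibble(taxon_a = character(), taxon_b = character(),
                  prevalence_a = integer(), prevalence_b = integer(),
                  co_count = integer(), p_value = numeric(),
                  significant = logical()))
  }
  K <- rowSums(m)
  co <- tcrossprod(m * 1)
  pair <- which(upper.tri(co), arr.ind = TRUE)
  x <- co[pair]
  ka <- K[pair[, 1]]; kb <- K[pair[, 2]]
  p <- phyper(x - 1, ka, N - ka, kb, lower.tail = FALSE)
  out <- tibble(taxon_a = rownames(m)[pair[, 1]],
                taxon_b = rownames(m)[pair[, 2]],
                prevalence_a = as.integer(ka), prevalence_b = as.integer(kb),
                co_count = as.integer(x), p_value = p)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' Partition a co-occurrence network into modules
#'
#' Builds the undirected simple graph of significant co-occurrence edges
#' and partitions its nodes by modularity maximization with the Leiden
#' algorithm. All modules are returned; the `reported` flag marks those
#' exceeding the reporting size (more than 10 taxa by default), the
#' convention used when describing recurrent community modules.
#'
#' @param edges An edge tibble from [cooccurrence_edges()] (its
#'   significant rows are used), or any tibble with `taxon_a`/`taxon_b`.
#' @param min_report_size Modules must exceed this many nodes to be
#'   flagged `reported` (default 10).
#' @param seed Integer seed for the Leiden heuristic.
#' @param resolution Resolution parameter of the modularity objective
#'   (default 1).
#' @return A tibble of class `euk_modules`: `module_id`, `n_nodes`,
#'   `n_edges`, `reported`, and a `members` list column. The igraph object
#'   and full membership vector are carried in attributes `"graph"` and
#'   `"membership"`.
#' @export
detect_modules <- function(edges, min_report_size = 10L, seed = 1L,
                           resolution = 1) {
  if (!all(c("taxon_a", "taxon_b") %in% names(edges))) {
    abort("edges need taxon_a and taxon_b columns")
  }
  if ("significant" %in% names(edges)) edges <- edges[edges$significant, ]
  empty <- tibble(module_id = integer(), n_nodes = integer(),
                  n_edges = integer(), reported = logical(),
                  members = list())
  if (nrow(edges) == 0) return(structure(empty, class = c("euk_modules", class(empty))))
  g <- igraph::graph_from_data_frame(edges[c("taxon_a", "taxon_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(comm)
  out <- purrr::map(sort(unique(as.integer(memb))), function(mod) {
    nodes <- names(memb)[memb == mod]
    sub <- igraph::induced_subgraph(g, nodes)
    tibble(module_id = mod, n_nodes = length(nodes),
           n_edges = igraph::ecount(sub),
           reported = length(nodes) > min_report_size,
           members = list(sort(nodes)))
  }) |> bind_rows() |> arrange(dplyr::desc(.data$n_nodes))
  attr(out, "graph") <- g
  attr(out, "membership") <- memb
  structure(out, class = c("euk_modules", class(out)))
}

#' @method autoplot euk_modules
#' @export
autoplot.euk_modules <- function(object, ...) {
  g <- attr(object, "graph")
  if (is.null(g) || igraph::vcount(g) == 0) abort("no network to plot")
  memb <- attr(object, "membership")
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  module = factor(as.integer(memb[igraph::V(g)$name])))
  el <- igraph::as_edgelist(g)
  segs <- tibble(x = nodes$x[match(el[, 1], nodes$name)],
                 y = nodes$y[match(el[, 1], nodes$name)],
                 xend = nodes$x[match(el[, 2], nodes$name)],
                 yend = nodes$y[match(el[, 2], nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$module), size = 2) +
    ggplot2::labs(title = "Co-occurrence network modules", colour = "module") +
    ggplot2::theme_void()
}

#' Stacked bp-fraction barplot across samples
#'
#' @param fractions Long fractions tibble from [bp_fractions()].
#' @return A ggplot object.
#' @export
plot_bp_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of mapped bp", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
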