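# Bin-quality scoring against a gold standard: which contigs enter the
# binner (FULL / EUK-only / OTHER-rem strategies), how much eukaryotic
# sequence ends up binned, purity/completeness/F1 of the eukaryotic bins,
# and a bp-weighted adjusted Rand index between bins and source genomes.

#' Validate a gold-standard contig-to-genome map
#'
#' @param goldmap Data frame with `contig_id`, `source_genome_id`,
#'   `genome_superkingdom`, `length_bp`.
#' @return The map as a tibble; errors on violations.
#' @export
validate_gold_map <- function(goldmap) {
  required <- c("contig_id", "source_genome_id", "genome_superkingdom", "length_bp")
  missing <- setdiff(required, names(goldmap))
  if (length(missing) > 0) {
    abort(paste0("gold map is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(goldmap)[required]
  if (anyDuplicated(x$contig_id) > 0) abort("gold map assigns a contig to >1 genome")
  if (any(x$length_bp < 1)) abort("gold map lengths must be positive")
  if (!all(x$genome_superkingdom %in% c("eukaryote", "prokaryote", "virus"))) {
    abort("genome_superkingdom must be eukaryote/prokaryote/virus")
  }
  x
}

#' Validate a contig-to-bin map
#'
#' @param binmap Data frame with `contig_id` and `bin_id`; unbinned contigs
#'   carry `NA` or `"unbinned"`.
#' @return Tibble with `bin_id` normalized to `NA` for unbinned contigs.
#' @export
validate_bin_map <- function(binmap) {
  required <- c("contig_id", "bin_id")
  missing <- setdiff(required, names(binmap))
  if (length(missing) > 0) {
    abort(paste0("bin map is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(binmap)[required]
  if (anyDuplicated(x$contig_id) > 0) abort("bin map assigns a contig to >1 bin")
  x$bin_id[x$bin_id %in% "unbinned"] <- NA_character_
  x
}

#' Select the contigs a binning strategy passes to the binner
#'
#' Three input strategies: bin the full assembly (`FULL`), bin only contigs
#' classified as eukaryotic (`EUK_only`), or bin eukaryotic plus
#' unclassified contigs, i.e. remove everything positively classified as
#' non-eukaryotic (`OTHER_rem`). A minimum-length cutoff — typically 1000,
#' 1500 or 3000 bp, matching common binner defaults — applies to every
#' strategy.
#'
#' @param manifest A contig manifest.
#' @param final_labels A final-label table covering the manifest.
#' @param mode `"FULL"`, `"EUK_only"` or `"OTHER_rem"`.
#' @param min_len Minimum contig length in bp (default 1000).
#' @return Character vector of retained contig ids (in manifest order).
#' @export
strategy_filter <- function(manifest, final_labels,
                            mode = c("FULL", "EUK_only", "OTHER_rem"),
                            min_len = 1000L) {
  mode <- arg_match(mode)
  manifest <- validate_contig_manifest(manifest)
  lab <- final_labels$final_label[match(manifest$contig_id, final_labels$contig_id)]
  if (anyNA(lab)) abort("final_labels must cover every manifest contig")
  keep <- manifest$length_bp >= min_len
  keep <- keep & switch(mode,
    FULL = TRUE,
    EUK_only = lab == "eukaryote",
    OTHER_rem = lab != "noneukaryote")
  manifest$contig_id[keep]
}

# bp (or unit) weight per contig of a gold map, honoring the weighting choice
.gold_weights <- function(goldmap, weighting) {
  if (weighting == "bp") as.numeric(goldmap$length_bp) else rep(1, nrow(goldmap))
}

.joined_bins <- function(binmap, goldmap) {
  binmap <- validate_bin_map(binmap)
  goldmap <- validate_gold_map(goldmap)
  unknown <- setdiff(binmap$contig_id, goldmap$contig_id)
  if (length(unknown) > 0) {
    abort(sprintf("bin map contains %d contig(s) absent from the gold map (e.g. '%s')",
                  length(unknown), unknown[1]))
  }
  inner_join(binmap, goldmap, by = "contig_id")
}

#' Identify the eukaryotic bins
#'
#' A bin is eukaryotic when more than half of its base pairs derive from
#' eukaryotic genomes (strict majority).
#'
#' @param binmap A contig-to-bin map.
#' @param goldmap The gold-standard contig-to-genome map.
#' @param weighting `"bp"` (default) or `"count"` (each contig weighs 1).
#' @return Character vector of eukaryotic bin ids.
#' @export
euk_bins <- function(binmap, goldmap, weighting = c("bp", "count")) {
  weighting <- arg_match(weighting)
  j <- .joined_bins(binmap, goldmap)
  j <- j[!is.na(j$bin_id), ]
  if (nrow(j) == 0) return(character(0))
  w <- .gold_weights(j, weighting)
  tot <- tapply(w, j$bin_id, sum)
  euk <- tapply(w * (j$genome_superkingdom == "eukaryote"), j$bin_id, sum)
  names(tot)[euk / tot > 0.5]
}

#' Fraction of eukaryotic base pairs that were binned
#'
#' @inheritParams euk_bins
#' @return A value in `[0, 1]`: eukaryote-genome bp assigned to any bin
#'   divided by the total eukaryote-genome bp in the (filtered) assembly.
#'   `NA` with a warning when the assembly holds no eukaryotic bp.
#' @export
pct_euk_bp_binned <- function(binmap, goldmap, weighting = c("bp", "count")) {
  weighting <- arg_match(weighting)
  j <- .joined_bins(binmap, goldmap)
  w <- .gold_weights(j, weighting)
  is_euk <- j$genome_superkingdom == "eukaryote"
  denom <- sum(w[is_euk])
  if (denom == 0) {
    warn("no eukaryotic bp in the assembly; fraction undefined")
    return(NA_real_)
  }
  sum(w[is_euk & !is.na(j$bin_id)]) / denom
}

#' Purity, completeness and F1 of eukaryotic bins
#'
#' Scores are restricted to eukaryotic bins (see [euk_bins()]) and are
#' bp-weighted by default. Purity of a bin is the bp share of its majority
#' genome; completeness of a genome in a bin is the bp of that genome in
#' the bin over the genome's total bp in the filtered assembly (fragments
#' below the binner's length cutoff were never candidates, so they do not
#' enter the denominator); F1 is their harmonic mean.
#'
#' Two variants: `"most_complete_bin"` reports one F1 per eukaryotic
#' genome, pairing the genome's most complete bin's completeness with that
#' bin's purity; `"all_bins"` reports one F1 per eukaryotic bin, scored
#' against its own majority genome. Summaries are unweighted means.
#'
#' @inheritParams euk_bins
#' @param variant `"most_complete_bin"` (default) or `"all_bins"`.
#' @return A list with `scores` (per-genome or per-bin tibble) and
#'   `summary` (one-row tibble of mean purity/completeness/F1). Empty, with
#'   a warning, when there are no eukaryotic bins.
#' @export
purity_completeness_f1 <- function(binmap, goldmap,
                                   variant = c("most_complete_bin", "all_bins"),
                                   weighting = c("bp", "count")) {
  variant <- arg_match(variant)
  weighting <- arg_match(weighting)
  j <- .joined_bins(binmap, goldmap)
  ebins <- euk_bins(binmap, goldmap, weighting)
  if (length(ebins) == 0) {
    warn("no eukaryotic bins to score")
    return(list(scores = tibble(), summary = tibble()))
  }
  j$w <- .gold_weights(j, weighting)
  inbin <- j[!is.na(j$bin_id) & j$bin_id %in% ebins, ]
  # bin x genome weight table
  cell <- inbin |>
    group_by(.data$bin_id, .data$source_genome_id, .data$genome_superkingdom) |>
    summarise(w = sum(.data$w), .groups = "drop")
  bin_tot <- cell |> group_by(.data$bin_id) |>
    summarise(bin_w = sum(.data$w), .groups = "drop")
  # genome totals over the whole filtered assembly (binned or not)
  gen_tot <- j |> group_by(.data$source_genome_id) |>
    summarise(gen_w = sum(.data$w), .groups = "drop")
  cell <- cell |> left_join(bin_tot, by = "bin_id") |>
    left_join(gen_tot, by = "source_genome_id") |>
    mutate(purity_share = .data$w / .data$bin_w,
           completeness = .data$w / .data$gen_w)
  bin_purity <- cell |> group_by(.data$bin_id) |>
    summarise(purity = max(.data$purity_share),
              majority_genome = .data$source_genome_id[which.max(.data$purity_share)],
              .groups = "drop")
  if (variant == "most_complete_bin") {
    scores <- cell |>
      filter(.data$genome_superkingdom == "eukaryote") |>
      group_by(.data$source_genome_id) |>
      dplyr::slice_max(.data$completeness, n = 1, with_ties = FALSE) |>
      ungroup() |>
      left_join(bin_purity[c("bin_id", "purity")], by = "bin_id") |>
      mutate(f1 = 2 * .data$purity * .data$completeness /
               (.data$purity + .data$completeness)) |>
      select(genome_id = "source_genome_id", bin_id = "bin_id",
             "purity", "completeness", "f1")
  } else {
    scores <- bin_purity |>
      left_join(cell |> select("bin_id", "source_genome_id", "completeness"),
                by = c("bin_id", majority_genome = "source_genome_id")) |>
      mutate(f1 = 2 * .data$purity * .data$completeness /
               (.data$purity + .data$completeness)) |>
      select("bin_id", genome_id = "majority_genome",
             "purity", "completeness", "f1")
  }
  list(scores = scores,
       summary = summarise(scores, purity = mean(.data$purity),
                           completeness = mean(.data$completeness),
                           f1 = mean(.data$f1)))
}

#' Adjusted Rand index between bins and source genomes, bp-weighted
#'
#' The standard chance-corrected Rand index computed on the contingency
#' table whose cell (i, j) holds the base pairs of genome i assigned to
#' bin j. Unbinned contigs are excluded: the index measures agreement on
#' the binned sequence only (including unbinned contigs as singletons
#' would change the values).
#'
#' @inheritParams euk_bins
#' @return A value `<= 1`; 1 iff the two partitions agree on the binned
#'   bp. A single-cell table is flagged degenerate with value 1.
#' @export
bin_ari <- function(binmap, goldmap, weighting = c("bp", "count")) {
  weighting <- arg_match(weighting)
  j <- .joined_bins(binmap, goldmap)
  j <- j[!is.na(j$bin_id), ]
  if (nrow(j) == 0) abort("no binned contigs: ARI undefined")
  w <- .gold_weights(j, weighting)
  tab <- tapply(w, list(j$source_genome_id, j$bin_id), sum, default = 0)
  ch2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sum_cells <- sum(ch2(tab))
  sum_rows <- sum(ch2(rowSums(tab)))
  sum_cols <- sum(ch2(colSums(tab)))
  expected <- sum_rows * sum_cols / ch2(n)
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) {
    # one genome in one bin (or equivalent): partitions agree trivially
    return(structure(1, degenerate = TRUE))
  }
  structure((sum_cells - expected) / (max_index - expected), degenerate = FALSE)
}

#' Score a binning end to end
#'
#' Convenience wrapper computing the fraction of eukaryotic bp binned,
#' both F1 variants and the bp-weighted ARI in one call.
#'
#' @inheritParams euk_bins
#' @return An object of class `bin_quality` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
evaluate_binning <- function(binmap, goldmap, weighting = c("bp", "count")) {
  weighting <- arg_match(weighting)
  mcb <- purity_completeness_f1(binmap, goldmap, "most_complete_bin", weighting)
  ab <- purity_completeness_f1(binmap, goldmap, "all_bins", weighting)
  structure(list(
    pct_euk_bp_binned = pct_euk_bp_binned(binmap, goldmap, weighting),
    ari = as.numeric(bin_ari(binmap, goldmap, weighting)),
    most_complete_bin = mcb, all_bins = ab,
    euk_bins = euk_bins(binmap, goldmap, weighting),
    weighting = weighting
  ), class = "bin_quality")
}

#' @export
print.bin_quality <- function(x, ...) {
  cat(sprintf("Binning quality (%s-weighted): %d eukaryotic bin(s)\n",
              x$weighting, length(x$euk_bins)))
  cat(sprintf("  eukaryotic bp binned: %.1f%%   ARI: %.3f\n",
              100 * x$pct_euk_bp_binned, x$ari))
  if (nrow(x$most_complete_bin$summary) > 0) {
    s <- x$most_complete_bin$summary
    cat(sprintf("  most-complete-bin means: purity %.3f, completeness %.3f, F1 %.3f\n",
                s$purity, s$completeness, s$f1))
  }
  invisible(x)
}

#' Tidy per-genome bin scores
#'
#' @param x A `bin_quality` object from [evaluate_binning()].
#' @param variant Which F1 variant's scores to return.
#' @param ... Unused.
#' @return A tibble of per-genome (or per-bin) purity/completeness/F1.
#' @method tidy bin_quality
#' @export
tidy.bin_quality <- function(x, variant = c("most_complete_bin", "all_bins"), ...) {
  variant <- arg_match(variant)
  x[[variant]]$scores
}

#' @rdname tidy.bin_quality
#' @method glance bin_quality
#' @export
glance.bin_quality <- function(x, ...) {
  s <- x$most_complete_bin$summary
  tibble(pct_euk_bp_binned = x$pct_euk_bp_binned, ari = x$ari,
         n_euk_bins = length(x$euk_bins),
         mean_purity = if (nrow(s)) s$purity else NA_real_,
         mean_completeness = if (nrow(s)) s$completeness else NA_real_,
         mean_f1 = if (nrow(s)) s$f1 else NA_real_)
}

#' @method autoplot bin_quality
#' @export
autoplot.bin_quality <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) abort("no eukaryotic bins to plot")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$completeness, y = .data$purity,
                                  size = .data$f1)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "completeness", y = "purity", size = "F1",
                  title = "Eukaryotic bin recovery") +
    ggplot2::theme_minimal()
}
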