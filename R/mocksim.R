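# Synthetic-data generator: mock-metagenome compositions with an imposed
# eukaryote:prokaryote bp ratio, fixed-length test contigs cut from a
# genome catalog, and classifier calls drawn from length-stratified error
# profiles. Stands in for genome retrieval, read simulation and the
# external classifiers so every downstream stage can be exercised and
# benchmarked from code alone.

#' Simulate a genome catalog
#'
#' Draws a catalog of eukaryotic and prokaryotic genomes with realistic
#' size scales (eukaryotic genomes tens of Mbp across tens of scaffolds;
#' prokaryotic genomes a few Mbp in a handful of replicons) from which test
#' contigs and mock compositions are sampled. Defaults mirror a benchmark
#' set of 33 eukaryotic and 216 prokaryotic genomes.
#'
#' @param n_euk,n_prok Number of eukaryotic / prokaryotic genomes.
#' @param euk_mean_bp,prok_mean_bp Median genome sizes (bp) on the log
#'   scale; genome sizes are lognormal around these.
#' @param euk_sdlog,prok_sdlog Lognormal sdlog of genome sizes.
#' @param seed Integer seed.
#' @return A tibble with columns `genome_id`, `superkingdom`,
#'   `total_length_bp` and a list column `contig_lengths` whose entries sum
#'   to `total_length_bp`.
#' @export
simulate_genome_catalog <- function(n_euk = 33L, n_prok = 216L,
                                    euk_mean_bp = 3e7, prok_mean_bp = 4e6,
                                    euk_sdlog = 0.8, prok_sdlog = 0.4,
                                    seed = 1L) {
  if (n_euk < 1 || n_prok < 1) abort("need at least one genome per superkingdom")
  set.seed(seed)
  one_kingdom <- function(n, kingdom, mean_bp, sdlog, n_contig_range) {
    sizes <- pmax(round(rlnorm(n, log(mean_bp), sdlog)), 50000)
    purrr::map2(sizes, sample(n_contig_range[1]:n_contig_range[2], n, replace = TRUE),
                function(total, k) {
                  # broken-stick split into k contigs, each at least 10 kbp
                  k <- min(k, max(1L, total %/% 20000L))
                  cuts <- sort(runif(k - 1))
                  lens <- round(diff(c(0, cuts, 1)) * total)
                  lens[lens < 10000] <- 10000
                  lens[length(lens)] <- lens[length(lens)] + (total - sum(lens))
                  if (lens[length(lens)] < 1) lens <- lens[lens > 0]
                  as.integer(lens)
                }) -> contigs
    tibble(genome_id = sprintf("%s_%03d", substr(kingdom, 1, 4), seq_len(n)),
           superkingdom = kingdom,
           total_length_bp = purrr::map_int(contigs, function(x) as.integer(sum(as.numeric(x)))),
           contig_lengths = contigs)
  }
  out <- bind_rows(
    one_kingdom(n_euk, "eukaryote", euk_mean_bp, euk_sdlog, c(10L, 60L)),
    one_kingdom(n_prok, "prokaryote", prok_mean_bp, prok_sdlog, c(1L, 10L))
  )
  validate_genome_catalog(out)
}

#' Validate a genome catalog
#'
#' @param catalog A data frame with `genome_id`, `superkingdom`,
#'   `total_length_bp`, `contig_lengths` (list of positive integers summing
#'   to the total).
#' @return The catalog as a tibble; errors on invariant violations.
#' @export
validate_genome_catalog <- function(catalog) {
  required <- c("genome_id", "superkingdom", "total_length_bp", "contig_lengths")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(catalog)
  if (nrow(x) == 0) abort("catalog is empty")
  if (anyDuplicated(x$genome_id) > 0) abort("duplicate genome_id in catalog")
  if (!all(x$superkingdom %in% c("eukaryote", "prokaryote"))) {
    abort("superkingdom must be eukaryote or prokaryote")
  }
  ok <- purrr::map2_lgl(x$contig_lengths, x$total_length_bp, function(lens, tot) {
    length(lens) > 0 && all(lens >= 1) && sum(as.numeric(lens)) == tot
  })
  if (!all(ok)) {
    abort(sprintf("contig_lengths of genome '%s' do not sum to total_length_bp",
                  x$genome_id[which(!ok)[1]]))
  }
  x
}

#' Sample mock-metagenome compositions
#'
#' Per sample, each genome's relative abundance is drawn from a lognormal
#' distribution; the bp share of a genome is abundance times genome length.
#' All eukaryotic abundances are then rescaled by a common factor so that
#' the realized eukaryote:prokaryote bp ratio equals `ratio` exactly in
#' every sample (the relative structure within each superkingdom is left
#' intact), and abundances are renormalized to sum to one.
#'
#' @param catalog A genome catalog with both superkingdoms present.
#' @param mu,sigma Lognormal log-scale parameters of per-genome abundance
#'   (defaults 1 and 2).
#' @param ratio Imposed eukaryote:prokaryote bp ratio (default 0.05).
#' @param n_samples Number of mock samples (default 15).
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `genome_id`, `superkingdom`,
#'   `abundance` (sums to 1 per sample) and `bp_share` (sums to 1 per
#'   sample; eukaryote over prokaryote share equals `ratio` exactly).
#' @export
sample_composition <- function(catalog, mu = 1, sigma = 2, ratio = 0.05,
                               n_samples = 15L, seed = 1L) {
  catalog <- validate_genome_catalog(catalog)
  if (sigma <= 0 || ratio <= 0) abort("sigma and ratio must be positive")
  kingdoms <- unique(catalog$superkingdom)
  if (!all(c("eukaryote", "prokaryote") %in% kingdoms)) {
    abort("catalog must contain both eukaryote and prokaryote genomes")
  }
  set.seed(seed)
  is_euk <- catalog$superkingdom == "eukaryote"
  len <- as.numeric(catalog$total_length_bp)
  purrr::map(seq_len(n_samples), function(s) {
    a <- rlnorm(nrow(catalog), meanlog = mu, sdlog = sigma)
    b <- a * len
    scale_euk <- ratio * sum(b[!is_euk]) / sum(b[is_euk])
    a[is_euk] <- a[is_euk] * scale_euk
    b <- a * len
    tibble(sample_id = sprintf("S%02d", s),
           genome_id = catalog$genome_id,
           superkingdom = catalog$superkingdom,
           abundance = a / sum(a),
           bp_share = b / sum(b),
           log_abundance_raw = log(ifelse(is_euk, a / scale_euk, a)))
  }) |> bind_rows()
}

#' Extract fixed-length test contigs from a genome catalog
#'
#' For each genome and each target length, cuts `n_per_genome` fragments
#' at uniform random start positions from source contigs long enough to
#' hold them (source contigs are chosen with probability proportional to
#' their number of valid start positions, so cut sites are uniform over
#' the eligible genome). Fragments may overlap. Genomes with no contig of
#' sufficient length are skipped for that target length with a warning.
#'
#' @param catalog A genome catalog.
#' @param lengths Target fragment lengths in bp (default 1000, 3000, 5000).
#' @param n_per_genome Fragments per genome per length (default 100).
#' @param seed Integer seed.
#' @param sequences Optional named list (by `genome_id`) of character
#'   vectors holding the contig sequences; when supplied, fragment
#'   sequences are returned in a `sequence` column.
#' @return A contig-manifest tibble (`contig_id`, `length_bp`,
#'   `true_label`, `source_genome_id`) plus provenance columns
#'   `source_contig` (index) and `start_bp` (1-based).
#' @export
extract_test_contigs <- function(catalog, lengths = c(1000L, 3000L, 5000L),
                                 n_per_genome = 100L, seed = 1L,
                                 sequences = NULL) {
  catalog <- validate_genome_catalog(catalog)
  set.seed(seed)
  rows <- list()
  for (g in seq_len(nrow(catalog))) {
    lens <- catalog$contig_lengths[[g]]
    gid <- catalog$genome_id[g]
    for (L in lengths) {
      eligible <- which(lens >= L)
      if (length(eligible) == 0) {
        warn(sprintf("genome '%s' has no contig of length >= %d; skipped for that length",
                     gid, L))
        next
      }
      w <- lens[eligible] - L + 1
      src <- eligible[sample.int(length(eligible), n_per_genome,
                                 replace = TRUE, prob = w)]
      start <- floor(runif(n_per_genome) * (lens[src] - L + 1)) + 1L
      rows[[length(rows) + 1L]] <- tibble(
        contig_id = sprintf("%s_L%d_f%03d", gid, L, seq_len(n_per_genome)),
        length_bp = as.integer(L),
        true_label = catalog$superkingdom[g],
        source_genome_id = gid,
        source_contig = src,
        start_bp = as.integer(start)
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no genome was eligible for any target length")
  if (!is.null(sequences)) {
    out$sequence <- purrr::pmap_chr(
      list(out$source_genome_id, out$source_contig, out$start_bp, out$length_bp),
      function(g, ci, st, L) substr(sequences[[g]][ci], st, st + L - 1L))
  }
  out
}

#' Length-stratified classifier error profile
#'
#' Defines, per contig-length bin, the probability that a tool calls a
#' true eukaryotic contig eukaryotic (`sensitivity`), a true
#' non-eukaryotic contig non-eukaryotic (`specificity`), and the
#' probability of abstaining (`unclassified_rate`, applied to both
#' classes). Bins are `[len_min[i], len_min[i+1])`, the last open-ended.
#'
#' @param tool_id Tool identifier.
#' @param len_min Increasing vector of bin lower edges (bp); first edge
#'   covers all shorter contigs.
#' @param sensitivity,specificity,unclassified_rate Per-bin probabilities
#'   (recycled if length 1). `sensitivity + unclassified_rate` and
#'   `specificity + unclassified_rate` must not exceed 1 in any bin.
#' @return A tibble of class `eukbench_profile`.
#' @export
error_profile <- function(tool_id, len_min = 0,
                          sensitivity = 0.9, specificity = 0.9,
                          unclassified_rate = 0) {
  k <- length(len_min)
  if (k == 0 || is.unsorted(len_min, strictly = TRUE)) {
    abort("len_min must be strictly increasing")
  }
  rec <- function(x) if (length(x) == 1) rep(x, k) else x
  sens <- rec(sensitivity); spec <- rec(specificity); uncl <- rec(unclassified_rate)
  if (length(sens) != k || length(spec) != k || length(uncl) != k) {
    abort("per-bin vectors must match the number of length bins")
  }
  if (any(c(sens, spec, uncl) < 0) || any(c(sens, spec, uncl) > 1) ||
      any(sens + uncl > 1 + 1e-12) || any(spec + uncl > 1 + 1e-12)) {
    abort("probabilities must lie in [0,1] with class rate + unclassified_rate <= 1")
  }
  structure(tibble(tool_id = tool_id, len_min = as.numeric(len_min),
                   sensitivity = sens, specificity = spec,
                   unclassified_rate = uncl),
            class = c("eukbench_profile", class(tibble())))
}

#' Default synthetic error profiles
#'
#' Emulates the characteristic behaviours observed when benchmarking real
#' classifiers: k-mer tools improve markedly with contig length and rarely
#' abstain; reference-based tools are near-perfect when they answer but
#' leave a large fraction of (especially eukaryotic) contigs unannotated.
#'
#' @return Named list of [error_profile()] objects for three k-mer-style
#'   tools and one reference-style tool.
#' @export
default_error_profiles <- function() {
  bins <- c(0, 3000, 5000)
  list(
    tiara = error_profile("tiara", bins,
                          sensitivity = c(0.80, 0.90, 0.95),
                          specificity = c(0.95, 0.97, 0.98),
                          unclassified_rate = c(0.05, 0.03, 0.02)),
    whokaryote = error_profile("whokaryote", bins,
                               sensitivity = c(0.75, 0.88, 0.93),
                               specificity = c(0.93, 0.96, 0.97),
                               unclassified_rate = c(0.05, 0.02, 0.02)),
    deepmicrobefinder = error_profile("deepmicrobefinder", bins,
                                      sensitivity = c(0.82, 0.91, 0.94),
                                      specificity = c(0.92, 0.95, 0.97),
                                      unclassified_rate = 0),
    kaiju = error_profile("kaiju", bins,
                          sensitivity = c(0.54, 0.59, 0.61),
                          specificity = c(0.54, 0.59, 0.61),
                          unclassified_rate = c(0.45, 0.40, 0.38))
  )
}

#' Simulate classifier calls from error profiles
#'
#' For each tool and contig, draws the tool's call from the contig's true
#' label and the tool's length-bin error rates: a true eukaryote is called
#' `eukaryote` with probability sensitivity, `unclassified` with the
#' abstention probability, else `noneukaryote`; symmetrically for true
#' non-eukaryotes via specificity.
#'
#' @param manifest A contig manifest with concrete true labels.
#' @param profiles A list of [error_profile()] objects (or a single one).
#' @param seed Integer seed.
#' @return A call table (`contig_id`, `tool_id`, `raw_label`,
#'   `norm_label`) with one row per contig per tool.
#' @export
simulate_calls <- function(manifest, profiles = default_error_profiles(),
                           seed = 1L) {
  manifest <- validate_contig_manifest(manifest)
  if (inherits(profiles, "eukbench_profile")) profiles <- list(profiles)
  if (any(manifest$true_label == "unknown")) {
    abort("simulate_calls needs concrete true labels (no 'unknown')")
  }
  set.seed(seed)
  is_pos <- manifest$true_label == "eukaryote"
  purrr::map(profiles, function(p) {
    bin <- findInterval(manifest$length_bp, p$len_min)
    bin[bin < 1] <- 1L
    hit <- ifelse(is_pos, p$sensitivity[bin], p$specificity[bin])
    uncl <- p$unclassified_rate[bin]
    u <- runif(nrow(manifest))
    call <- ifelse(u < hit,
                   ifelse(is_pos, "eukaryote", "noneukaryote"),
                   ifelse(u < hit + uncl, "unclassified",
                          ifelse(is_pos, "noneukaryote", "eukaryote")))
    tibble(contig_id = manifest$contig_id, tool_id = p$tool_id[1],
           raw_label = call, norm_label = call)
  }) |> bind_rows()
}

#' Simulate per-sample contig coverage from a mock composition
#'
#' Produces the coverage table the community statistics consume: per
#' sample and contig, a mean read depth and a breadth of coverage, plus a
#' per-sample Nonpareil-style coverage scalar. A contig's expected depth
#' is proportional to its genome's abundance in the sample; breadth
#' follows the Poisson-coverage relation `1 - exp(-depth)` sharpened by
#' `breadth_shape`, so low-abundance genomes yield the patchy, spurious
#' mappings the 25% breadth rule is designed to reject.
#'
#' @param manifest A contig manifest whose `source_genome_id`s appear in
#'   the composition.
#' @param composition A composition from [sample_composition()].
#' @param depth_scale Mean depth (x) of an averagely abundant genome
#'   (default 5).
#' @param breadth_shape Exponent applied to the Poisson breadth (default
#'   1; larger values depress the breadth of shallow contigs).
#' @param overdispersion Gamma noise on per-contig depth (squared
#'   coefficient of variation, default 0.3).
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `contig_id`, `mean_depth`, `breadth`,
#'   with per-sample `nonpareil_coverage` carried as an attached
#'   `samples` attribute (tibble `sample_id`, `nonpareil_coverage`).
#' @export
simulate_coverage <- function(manifest, composition, depth_scale = 5,
                              breadth_shape = 1, overdispersion = 0.3,
                              seed = 1L) {
  manifest <- validate_contig_manifest(manifest)
  need <- c("sample_id", "genome_id", "abundance")
  if (!all(need %in% names(composition))) {
    abort("composition needs sample_id, genome_id and abundance columns")
  }
  missing <- setdiff(unique(manifest$source_genome_id),
                     unique(composition$genome_id))
  if (length(missing) > 0) {
    abort(sprintf("composition lacks genome(s) named in the manifest (e.g. '%s')",
                  missing[1]))
  }
  set.seed(seed)
  samples <- unique(composition$sample_id)
  out <- purrr::map(samples, function(s) {
    comp_s <- composition[composition$sample_id == s, ]
    a <- comp_s$abundance[match(manifest$source_genome_id, comp_s$genome_id)]
    lambda <- depth_scale * a / mean(comp_s$abundance)
    shape <- 1 / overdispersion
    depth <- stats::rgamma(length(lambda), shape = shape,
                           rate = shape / pmax(lambda, 1e-12))
    breadth <- (1 - exp(-depth))^breadth_shape
    breadth[depth == 0] <- 0
    tibble(sample_id = s, contig_id = manifest$contig_id,
           mean_depth = depth, breadth = breadth)
  }) |> bind_rows()
  per_sample <- out |>
    group_by(.data$sample_id) |>
    summarise(total_depth = sum(.data$mean_depth), .groups = "drop") |>
    mutate(nonpareil_coverage = 1 - exp(-.data$total_depth /
                                          stats::median(.data$total_depth))) |>
    select("sample_id", "nonpareil_coverage")
  attr(out, "samples") <- per_sample
  out
}
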