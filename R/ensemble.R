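# Hybrid ensemble classifier: a reference-based call takes precedence when
# the contig is long enough to trust it; otherwise a majority vote over
# k-mer-based tools decides, under a stricter length threshold; anything
# below the reference threshold stays unclassified.

#' Ensemble configuration
#'
#' @param kmer_tools Character vector of k-mer-based tool ids whose votes
#'   are combined (at least one; two or more for a meaningful vote). The
#'   default trio reflects the best-performing combination of composition
#'   classifiers without a reference database.
#' @param ref_tool Tool id of the reference-based classifier whose calls
#'   take precedence.
#' @param min_len_ref_bp Minimum contig length (bp) for a reference-based
#'   call to be used. Default 1000.
#' @param min_len_kmer_bp Minimum contig length (bp) for the k-mer vote to
#'   be used. Default 3000. Must be at least `min_len_ref_bp`.
#' @return A list of class `eukbench_config`.
#' @export
ensemble_config <- function(kmer_tools = c("tiara", "whokaryote", "deepmicrobefinder"),
                            ref_tool = "kaiju",
                            min_len_ref_bp = 1000L,
                            min_len_kmer_bp = 3000L) {
  if (length(kmer_tools) < 1 || anyNA(kmer_tools)) {
    abort("kmer_tools must name at least one tool")
  }
  if (length(ref_tool) != 1 || is.na(ref_tool)) {
    abort("ref_tool must be a single tool id")
  }
  if (min_len_ref_bp < 1 || min_len_kmer_bp < 1) {
    abort("length thresholds must be positive")
  }
  if (min_len_ref_bp > min_len_kmer_bp) {
    abort("min_len_ref_bp must not exceed min_len_kmer_bp")
  }
  structure(list(kmer_tools = as.character(kmer_tools),
                 ref_tool = as.character(ref_tool),
                 min_len_ref_bp = as.integer(min_len_ref_bp),
                 min_len_kmer_bp = as.integer(min_len_kmer_bp)),
            class = "eukbench_config")
}

#' Majority vote over k-mer classifier calls, ties excluded
#'
#' Unclassified votes are discarded before counting. The strict-majority
#' label among the remaining votes wins; an exact tie, or no informative
#' vote at all, yields `unclassified`. No tool is senior: ties are never
#' broken.
#'
#' @param votes Character vector of normalized labels, one per tool
#'   (`eukaryote`, `noneukaryote`, `unclassified`). A missing tool should
#'   be encoded as an `unclassified` vote.
#' @return A single normalized label.
#' @export
#' @examples
#' majority_vote(c("eukaryote", "eukaryote", "noneukaryote"))
#' majority_vote(c("eukaryote", "noneukaryote", "unclassified")) # tie
majority_vote <- function(votes) {
  if (length(votes) == 0) abort("empty vote list: configure at least one k-mer tool")
  bad <- !votes %in% .norm_labels
  if (anyNA(votes) || any(bad)) {
    abort("votes must be eukaryote/noneukaryote/unclassified")
  }
  n_euk <- sum(votes == "eukaryote")
  n_non <- sum(votes == "noneukaryote")
  if (n_euk > n_non) "eukaryote"
  else if (n_non > n_euk) "noneukaryote"
  else "unclassified"
}

#' Classify one contig with the hybrid reference-first rule
#'
#' @param length_bp Contig length in base pairs.
#' @param ref_call Normalized label from the reference-based tool
#'   (`unclassified` when the tool produced no annotation).
#' @param kmer_votes Character vector of k-mer tool votes.
#' @param cfg An [ensemble_config()].
#' @return A one-row tibble with `final_label` and `decided_by`
#'   (`reference`, `kmer_vote`, or `none`).
#' @details A reference call — eukaryote or noneukaryote alike — takes
#'   precedence whenever the contig reaches `min_len_ref_bp`; the k-mer
#'   vote is consulted only for contigs of at least `min_len_kmer_bp` that
#'   the reference tool left unannotated.
#' @export
hybrid_classify <- function(length_bp, ref_call, kmer_votes, cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "eukbench_config"))
  if (length(length_bp) != 1 || is.na(length_bp) || length_bp < 1) {
    abort("length_bp must be a single positive number")
  }
  if (length_bp >= cfg$min_len_ref_bp && ref_call != "unclassified") {
    if (!ref_call %in% .norm_labels) abort("ref_call must be a normalized label")
    return(tibble(final_label = ref_call, decided_by = "reference"))
  }
  if (length_bp >= cfg$min_len_kmer_bp) {
    v <- majority_vote(kmer_votes)
    return(tibble(final_label = v,
                  decided_by = if (v == "unclassified") "none" else "kmer_vote"))
  }
  tibble(final_label = "unclassified", decided_by = "none")
}

#' Classify every contig of an assembly
#'
#' Applies the hybrid rule across a whole manifest given a call table.
#' Tools with no row for a contig contribute an `unclassified` vote
#' (reference tools simply skip contigs without database hits).
#'
#' @param manifest A contig manifest (see [read_contig_manifest()]).
#' @param calls A call table covering any subset of the manifest's contigs.
#' @param cfg An [ensemble_config()].
#' @return A tibble with one row per manifest contig: `contig_id`,
#'   `final_label`, `decided_by`. Deterministic given its inputs.
#' @export
classify_assembly <- function(manifest, calls, cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "eukbench_config"))
  manifest <- validate_contig_manifest(manifest)
  calls <- validate_call_table(calls)
  unknown <- setdiff(unique(calls$contig_id), manifest$contig_id)
  if (length(unknown) > 0) {
    abort(sprintf("call table refers to %d contig(s) absent from the manifest (e.g. '%s')",
                  length(unknown), unknown[1]))
  }
  n <- nrow(manifest)
  lab_for <- function(tool) {
    sub <- calls[calls$tool_id == tool, ]
    out <- rep("unclassified", n)
    idx <- match(sub$contig_id, manifest$contig_id)
    out[idx] <- sub$norm_label
    out
  }
  ref <- lab_for(cfg$ref_tool)
  n_euk <- n_non <- integer(n)
  for (tool in cfg$kmer_tools) {
    v <- lab_for(tool)
    n_euk <- n_euk + (v == "eukaryote")
    n_non <- n_non + (v == "noneukaryote")
  }
  vote <- rep("unclassified", n)
  vote[n_euk > n_non] <- "eukaryote"
  vote[n_non > n_euk] <- "noneukaryote"

  len <- manifest$length_bp
  use_ref <- len >= cfg$min_len_ref_bp & ref != "unclassified"
  use_vote <- !use_ref & len >= cfg$min_len_kmer_bp

  final <- rep("unclassified", n)
  final[use_ref] <- ref[use_ref]
  final[use_vote] <- vote[use_vote]
  decided <- rep("none", n)
  decided[use_ref] <- "reference"
  decided[use_vote & final != "unclassified"] <- "kmer_vote"

  tibble(contig_id = manifest$contig_id, final_label = final, decided_by = decided)
}
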