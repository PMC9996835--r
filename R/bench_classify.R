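# Imbalance-aware evaluation of eukaryote-vs-rest classification:
# ratio-constrained subsampling repeated many times, scored by the
# Matthews correlation coefficient, precision and recall. The positive
# class is always the eukaryote.

#' Confusion counts for eukaryote classification
#'
#' @param predicted A final-label table (`contig_id`, `final_label`).
#' @param truth A contig manifest covering the same contig ids.
#' @param unclassified_mode How to treat `unclassified` predictions:
#'   `"as_negative"` (counted as non-eukaryote calls; the end-to-end view)
#'   or `"exclude"` (those contigs are dropped before counting; the view a
#'   reference-based tool's headline numbers imply).
#' @return A one-row tibble with `TP`, `FP`, `TN`, `FN` and `n_used`.
#'   True labels `prokaryote` and `virus` both count as negatives.
#' @export
confusion_counts <- function(predicted, truth,
                             unclassified_mode = c("as_negative", "exclude")) {
  unclassified_mode <- arg_match(unclassified_mode)
  truth <- validate_contig_manifest(truth)
  if (!all(c("contig_id", "final_label") %in% names(predicted))) {
    abort("predicted needs columns contig_id and final_label")
  }
  if (nrow(predicted) != nrow(truth) ||
      !setequal(predicted$contig_id, truth$contig_id)) {
    abort("predicted and truth must cover the same contig ids")
  }
  m <- match(truth$contig_id, predicted$contig_id)
  pred <- predicted$final_label[m]
  pos <- truth$true_label == "eukaryote"
  if (unclassified_mode == "exclude") {
    keep <- pred != "unclassified"
    pred <- pred[keep]; pos <- pos[keep]
  }
  pred_pos <- pred == "eukaryote"
  tibble(TP = sum(pred_pos & pos), FP = sum(pred_pos & !pos),
         TN = sum(!pred_pos & !pos), FN = sum(!pred_pos & pos),
         n_used = length(pred))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor of the denominator is zero the value is defined as 0 and the
#' `"degenerate"` attribute is set, so callers can distinguish a true zero
#' correlation from an undefined one.
#'
#' @param TP,FP,TN,FN Non-negative counts.
#' @return A single value in `[-1, 1]`, with attribute `degenerate`.
#' @export
mcc <- function(TP, FP, TN, FN) {
  .check_counts(TP, FP, TN, FN)
  # products overflow integer range on large assemblies; work in doubles
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom2 == 0) return(structure(0, degenerate = TRUE))
  structure((TP * TN - FP * FN) / sqrt(denom2), degenerate = FALSE)
}

#' @rdname mcc
#' @export
precision <- function(TP, FP, TN, FN) {
  .check_counts(TP, FP, TN, FN)
  if (TP + FP == 0) return(structure(0, degenerate = TRUE))
  structure(TP / (TP + FP), degenerate = FALSE)
}

#' @rdname mcc
#' @export
recall <- function(TP, FP, TN, FN) {
  .check_counts(TP, FP, TN, FN)
  if (TP + FN == 0) return(structure(0, degenerate = TRUE))
  structure(TP / (TP + FN), degenerate = FALSE)
}

.check_counts <- function(TP, FP, TN, FN) {
  x <- c(TP, FP, TN, FN)
  if (length(x) != 4 || anyNA(x) || any(x < 0)) {
    abort("confusion counts must be four non-negative numbers")
  }
  invisible(NULL)
}

#' Subsample contigs to a target eukaryote:prokaryote bp ratio
#'
#' Randomly removes contigs of the over-represented class, one at a time,
#' until the realized eukaryote:prokaryote base-pair ratio first crosses
#' the target; every contig of the other class is retained. With a target
#' of 0.05 this reproduces the class imbalance typical of environmental
#' metagenomes, so that performance estimates are representative of
#' real-world deployments rather than of balanced test sets.
#'
#' @param manifest A contig manifest with both classes present
#'   (`prokaryote` and `virus` jointly form the non-eukaryote side).
#' @param ratio Target eukaryote/non-eukaryote bp ratio (default 0.05).
#' @param seed Optional integer seed (set it for reproducibility; leave
#'   `NULL` inside a caller that manages the RNG stream).
#' @return Character vector of retained contig ids.
#' @export
subsample_to_ratio <- function(manifest, ratio = 0.05, seed = NULL) {
  manifest <- validate_contig_manifest(manifest)
  if (!is.null(seed)) set.seed(seed)
  is_euk <- manifest$true_label == "eukaryote"
  if (!any(is_euk) || all(is_euk)) {
    abort("both eukaryote and non-eukaryote contigs are required")
  }
  bp_euk <- sum(as.numeric(manifest$length_bp[is_euk]))
  bp_other <- sum(as.numeric(manifest$length_bp[!is_euk]))
  current <- bp_euk / bp_other
  if (current > ratio) {
    # drop eukaryote contigs until the ratio first reaches <= target
    idx <- which(is_euk)[sample.int(sum(is_euk))]
    remaining <- bp_euk - cumsum(as.numeric(manifest$length_bp[idx]))
    n_drop <- which(remaining / bp_other <= ratio)[1]
    if (is.na(n_drop)) n_drop <- length(idx)
    keep <- setdiff(seq_len(nrow(manifest)), idx[seq_len(n_drop)])
  } else if (current < ratio) {
    idx <- which(!is_euk)[sample.int(sum(!is_euk))]
    remaining <- bp_other - cumsum(as.numeric(manifest$length_bp[idx]))
    n_drop <- which(bp_euk / remaining >= ratio)[1]
    if (is.na(n_drop)) n_drop <- length(idx) - 1L  # never drop the whole class
    keep <- setdiff(seq_len(nrow(manifest)), idx[seq_len(n_drop)])
  } else {
    keep <- seq_len(nrow(manifest))
  }
  manifest$contig_id[sort(keep)]
}

#' Evaluate a classifier under repeated ratio-constrained subsampling
#'
#' Per repeat: subsample the benchmark set to the target bp ratio, form
#' the confusion matrix, and score MCC, precision and recall; report the
#' mean and standard deviation of each metric over repeats.
#'
#' @inheritParams confusion_counts
#' @param ratio Target eukaryote:prokaryote bp ratio (default 0.05).
#' @param n_repeats Number of subsampling repeats (default 100).
#' @param seed Integer seed governing all repeats.
#' @return An object of class `euk_metrics`: a list with `summary` (tibble
#'   of per-metric mean/sd), `repeats` (per-repeat confusion counts and
#'   metrics) and the evaluation settings. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
evaluate_classifier <- function(predicted, truth, ratio = 0.05,
                                n_repeats = 100L, seed = 1L,
                                unclassified_mode = c("as_negative", "exclude")) {
  unclassified_mode <- arg_match(unclassified_mode)
  truth <- validate_contig_manifest(truth)
  set.seed(seed)
  reps <- purrr::map(seq_len(n_repeats), function(i) {
    ids <- subsample_to_ratio(truth, ratio = ratio, seed = NULL)
    sub_truth <- truth[truth$contig_id %in% ids, ]
    sub_pred <- predicted[predicted$contig_id %in% ids, ]
    cc <- confusion_counts(sub_pred, sub_truth, unclassified_mode)
    mutate(cc, repeat_id = i,
           mcc = as.numeric(mcc(.data$TP, .data$FP, .data$TN, .data$FN)),
           precision = as.numeric(precision(.data$TP, .data$FP, .data$TN, .data$FN)),
           recall = as.numeric(recall(.data$TP, .data$FP, .data$TN, .data$FN)))
  }) |> bind_rows()
  long <- tidyr::pivot_longer(reps[c("repeat_id", "mcc", "precision", "recall")],
                              -"repeat_id", names_to = "metric")
  summary <- long |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop") |>
    mutate(n_repeats = n_repeats)
  structure(list(summary = summary, repeats = reps,
                 settings = list(ratio = ratio, n_repeats = n_repeats,
                                 seed = seed,
                                 unclassified_mode = unclassified_mode)),
            class = "euk_metrics")
}

#' @export
print.euk_metrics <- function(x, ...) {
  cat(sprintf("Eukaryote classification benchmark (%d subsampling repeats, bp ratio %.3g, unclassified %s)\n",
              x$settings$n_repeats, x$settings$ratio,
              x$settings$unclassified_mode))
  print(x$summary)
  invisible(x)
}

#' Tidy the per-repeat metrics of a classification benchmark
#'
#' @param x An `euk_metrics` object from [evaluate_classifier()].
#' @param ... Unused.
#' @return A tibble with one row per repeat and metric.
#' @method tidy euk_metrics
#' @export
tidy.euk_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$repeats[c("repeat_id", "mcc", "precision", "recall")],
                      -"repeat_id", names_to = "metric", values_to = "value")
}

#' @rdname tidy.euk_metrics
#' @return For `glance`: a one-row tibble with the mean of each metric,
#'   its sd, and the settings.
#' @method glance euk_metrics
#' @export
glance.euk_metrics <- function(x, ...) {
  s <- x$summary
  tibble(mcc = s$mean[s$metric == "mcc"],
         mcc_sd = s$sd[s$metric == "mcc"],
         precision = s$mean[s$metric == "precision"],
         recall = s$mean[s$metric == "recall"],
         n_repeats = x$settings$n_repeats,
         ratio = x$settings$ratio,
         unclassified_mode = x$settings$unclassified_mode)
}

#' @method autoplot euk_metrics
#' @export
autoplot.euk_metrics <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Classification performance over subsampling repeats") +
    ggplot2::theme_minimal()
}
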