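# Table I/O: contig manifests, call tables, and the classifier-output
# dialects they are normalized from. Canonical on-disk format is UTF-8
# tab-separated text with a header row and "." for empty fields.

.read_tsv_dot <- function(path, col_types) {
  readr::read_tsv(path, na = c(".", ""), col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

.write_tsv_dot <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::everything(), function(v) {
    v <- as.character(v)
    dplyr::if_else(is.na(v) | v == "", ".", v)
  }))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a contig manifest
#'
#' A contig manifest records, per contig, its identifier, its length in
#' base pairs, its true superkingdom label (for benchmark sets; `unknown`
#' for real assemblies) and, where known, the genome the contig derives
#' from. It is the backbone table the classifier, the benchmarks and the
#' community statistics all join against.
#'
#' @param path Path to a tab-separated file with header columns
#'   `contig_id`, `length_bp`, `true_label`, `source_genome_id`.
#'   Empty fields are written as `"."`.
#' @return A tibble with one validated row per contig.
#' @details Validation enforces: unique `contig_id`; `length_bp` a positive
#'   integer; `true_label` one of `eukaryote`, `prokaryote`, `virus`,
#'   `unknown`; and a non-empty `source_genome_id` for every contig whose
#'   true label is a concrete superkingdom.
#' @seealso [write_contig_manifest()], [validate_contig_manifest()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_contig_manifest(
#'   tibble::tibble(contig_id = c("c1", "c2"), length_bp = c(1500L, 4000L),
#'                  true_label = c("eukaryote", "prokaryote"),
#'                  source_genome_id = c("g1", "g2")), tf)
#' read_contig_manifest(tf)
read_contig_manifest <- function(path) {
  suppressWarnings(x <- .read_tsv_dot(path, readr::cols(
    contig_id = readr::col_character(),
    length_bp = readr::col_double(),
    true_label = readr::col_character(),
    source_genome_id = readr::col_character()
  )))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed manifest row at line %d of '%s': expected %s",
                  probs$row[1], path, probs$expected[1]))
  }
  validate_contig_manifest(x)
}

#' Validate a contig manifest
#'
#' @param manifest A data frame with manifest columns (see
#'   [read_contig_manifest()]).
#' @return The manifest as a tibble, invisibly checked; errors on any
#'   invariant violation.
#' @export
validate_contig_manifest <- function(manifest) {
  required <- c("contig_id", "length_bp", "true_label", "source_genome_id")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as_tibble(manifest)[required]
  if (anyNA(x$contig_id)) abort("manifest has empty contig_id")
  if (anyDuplicated(x$contig_id) > 0) {
    dup <- x$contig_id[duplicated(x$contig_id)][1]
    abort(sprintf("duplicate contig_id in manifest: '%s'", dup))
  }
  if (anyNA(x$length_bp) || any(x$length_bp < 1) ||
      any(x$length_bp != floor(x$length_bp))) {
    abort("length_bp must be a positive integer for every contig")
  }
  bad <- !x$true_label %in% .true_labels
  if (anyNA(x$true_label) || any(bad)) {
    abort(sprintf("unknown true_label '%s' (expected %s)",
                  x$true_label[which(is.na(x$true_label) | bad)][1],
                  paste(.true_labels, collapse = "/")))
  }
  need_src <- x$true_label %in% c("eukaryote", "prokaryote", "virus")
  if (any(need_src & (is.na(x$source_genome_id) | x$source_genome_id == ""))) {
    abort("benchmark contigs with a concrete true_label need a source_genome_id")
  }
  x$length_bp <- as.integer(x$length_bp)
  x
}

#' Write a contig manifest
#'
#' @param manifest A manifest tibble (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_manifest <- function(manifest, path) {
  .write_tsv_dot(validate_contig_manifest(manifest), path)
}

#' Read a normalized call table
#'
#' @param path Tab-separated file with columns `contig_id`, `tool_id`,
#'   `raw_label`, `norm_label`.
#' @return A validated call-table tibble.
#' @export
read_call_table <- function(path) {
  x <- .read_tsv_dot(path, readr::cols(
    contig_id = readr::col_character(),
    tool_id = readr::col_character(),
    raw_label = readr::col_character(),
    norm_label = readr::col_character()
  ))
  validate_call_table(x)
}

#' Validate a call table
#'
#' Per-contig, per-tool predictions in the normalized vocabulary
#' `eukaryote` / `noneukaryote` / `unclassified`. The pair
#' (`contig_id`, `tool_id`) must be unique.
#'
#' @param calls A data frame of calls.
#' @return The calls as a tibble; errors on invariant violation.
#' @export
validate_call_table <- function(calls) {
  required <- c("contig_id", "tool_id", "raw_label", "norm_label")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    abort(paste0("call table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as_tibble(calls)[required]
  key <- paste(x$contig_id, x$tool_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort("call table has duplicate (contig_id, tool_id) pairs")
  }
  bad <- !x$norm_label %in% .norm_labels
  if (anyNA(x$norm_label) || any(bad)) {
    abort("norm_label must be eukaryote/noneukaryote/unclassified")
  }
  x
}

#' @rdname read_call_table
#' @param calls A validated call table.
#' @export
write_call_table <- function(calls, path) {
  .write_tsv_dot(validate_call_table(calls), path)
}

# --- classifier-output dialects ---------------------------------------------

# Each dialect declares how to locate the contig id and raw label in the
# tool's native output, and how raw labels map onto the normalized
# vocabulary. Multi-class outputs (bacteria/archaea/organelle/virus)
# collapse onto "noneukaryote" because the task is binary eukaryote
# identification. Maps are plain lists so users can edit or extend them.

.default_dialects <- function() {
  list(
    tiara = list(
      id_col = "sequence_id", label_col = "class_fst_stage",
      label_map = c(eukarya = "eukaryote", archaea = "noneukaryote",
                    bacteria = "noneukaryote", prokarya = "noneukaryote",
                    organelle = "noneukaryote", mitochondrion = "noneukaryote",
                    plastid = "noneukaryote", unknown = "unclassified")
    ),
    whokaryote = list(
      id_col = "contig", label_col = "predicted",
      label_map = c(eukaryote = "eukaryote", prokaryote = "noneukaryote")
    ),
    # Score table: the predicted class is the column with the highest score.
    deepmicrobefinder = list(
      id_col = "Sequence Name", score_cols = TRUE,
      label_map = c(Eukaryote = "eukaryote", EukaryoteVirus = "noneukaryote",
                    Prokaryote = "noneukaryote", ProkaryoteVirus = "noneukaryote",
                    Plasmid = "noneukaryote")
    ),
    # C/U status flag; unclassified rows carry no usable taxon label.
    kaiju = list(
      id_col = "contig_id", label_col = "taxon_name", status_col = "status",
      label_map = c(Eukaryota = "eukaryote", Bacteria = "noneukaryote",
                    Archaea = "noneukaryote", Viruses = "noneukaryote")
    ),
    # Superkingdom extracted from the lineage-name column; how lineages
    # below superkingdom collapse is deliberately user-editable.
    cat = list(
      id_col = "contig", label_col = "superkingdom",
      label_map = c(Eukaryota = "eukaryote", Bacteria = "noneukaryote",
                    Archaea = "noneukaryote", Viruses = "noneukaryote",
                    `no support` = "unclassified")
    ),
    normalized = list(
      id_col = "contig_id", label_col = "raw_label",
      label_map = setNames(.norm_labels, .norm_labels)
    )
  )
}

#' Built-in classifier-output dialects
#'
#' @return A named list of dialect configurations. Each entry declares the
#'   contig-id column, the label column (or, for score tables, that the
#'   label is the arg-max score column) and the raw-to-normalized label map.
#' @export
eukbench_dialects <- function() .default_dialects()

#' Normalize a classifier output table into the common call vocabulary
#'
#' Classifier outputs come in heterogeneous shapes: two-column class
#' tables, score matrices, classified/unclassified flags plus taxon names,
#' lineage tables. This parses any supported dialect and emits one row per
#' input row with a `norm_label` in `eukaryote` / `noneukaryote` /
#' `unclassified`. Raw labels without a map entry become `unclassified`
#' with a warning; no row is ever dropped.
#'
#' @param raw_table Path to the tool's output file, or a data frame already
#'   holding it.
#' @param dialect One of `"tiara"`, `"whokaryote"`, `"deepmicrobefinder"`,
#'   `"kaiju"`, `"cat"`, `"normalized"`, or a name present in `dialects`.
#' @param tool_id Tool identifier stamped on the output rows; defaults to
#'   the dialect name.
#' @param dialects Dialect configuration list; defaults to
#'   [eukbench_dialects()] and may be edited to retarget columns or labels.
#' @return A call-table tibble (`contig_id`, `tool_id`, `raw_label`,
#'   `norm_label`) with exactly as many rows as the input.
#' @export
normalize_calls <- function(raw_table, dialect, tool_id = dialect,
                            dialects = eukbench_dialects()) {
  if (!is.character(dialect) || length(dialect) != 1 ||
      !dialect %in% names(dialects)) {
    abort(sprintf("unknown dialect '%s' (available: %s)",
                  as.character(dialect)[1],
                  paste(names(dialects), collapse = ", ")))
  }
  cfg <- dialects[[dialect]]
  x <- if (is.character(raw_table) && length(raw_table) == 1) {
    readr::read_tsv(raw_table, col_types = readr::cols(.default = readr::col_guess()),
                    progress = FALSE, show_col_types = FALSE)
  } else {
    as_tibble(raw_table)
  }
  if (!cfg$id_col %in% names(x)) {
    abort(sprintf("dialect '%s' expects an id column '%s'", dialect, cfg$id_col))
  }
  ids <- as.character(x[[cfg$id_col]])
  if (isTRUE(cfg$score_cols)) {
    score_names <- intersect(names(cfg$label_map), names(x))
    if (length(score_names) == 0) {
      abort(sprintf("dialect '%s' found none of its score columns", dialect))
    }
    scores <- as.matrix(x[score_names])
    raw <- score_names[max.col(scores, ties.method = "first")]
  } else {
    if (!cfg$label_col %in% names(x)) {
      abort(sprintf("dialect '%s' expects a label column '%s'",
                    dialect, cfg$label_col))
    }
    raw <- as.character(x[[cfg$label_col]])
  }
  norm <- unname(cfg$label_map[raw])
  if (!is.null(cfg$status_col) && cfg$status_col %in% names(x)) {
    unhit <- x[[cfg$status_col]] %in% c("U", "u")
    norm[unhit] <- "unclassified"
    raw[unhit] <- raw[unhit] %||% NA_character_
  }
  unmapped <- is.na(norm)
  if (!is.null(cfg$status_col)) {
    unmapped <- unmapped & !(x[[cfg$status_col]] %in% c("U", "u"))
  }
  if (any(unmapped)) {
    warn(sprintf(
      "%d row(s) with raw label(s) outside the '%s' map (e.g. '%s'); set to unclassified",
      sum(unmapped), dialect, raw[unmapped][1]))
  }
  norm[is.na(norm)] <- "unclassified"
  validate_call_table(tibble(
    contig_id = ids, tool_id = tool_id,
    raw_label = dplyr::coalesce(raw, "."), norm_label = norm
  ))
}
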