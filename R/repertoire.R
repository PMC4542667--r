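#' Translate CDR3 junction nucleotide sequences
#'
#' Translates in-frame junctions with the standard genetic code; out-of-frame
#' or empty junctions yield `NA`. Stop codons appear as `*` in the output.
#'
#' @param junction Character vector of nucleotide sequences over A/C/G/T.
#' @return Character vector of amino-acid sequences (`NA` where out of frame).
#' @export
translate_junction <- function(junction) {
  out <- rep(NA_character_, length(junction))
  ok <- !is.na(junction) & nchar(junction) > 0 & nchar(junction) %% 3 == 0
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(junction[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

#' Clone identity key
#'
#' A clone is identified by its V gene (allele suffix stripped, so
#' `TRBV12-3*01` and `TRBV12-3*02` collapse) together with the CDR3
#' nucleotide sequence. Equal keys mean "same clone" everywhere in the
#' pipeline, including across platforms, tissues and timepoints.
#'
#' @param v_call Character vector of V gene calls (IMGT-style, with or
#'   without `*allele` suffix).
#' @param junction Character vector of CDR3 nucleotide sequences.
#' @return Character vector of clone keys.
#' @export
make_clone_key <- function(v_call, junction) {
  if (any(is.na(junction) | !nzchar(junction))) {
    abort("junction must be a non-empty nucleotide string",
          class = "clonetrackr_error_empty_junction")
  }
  paste(sub("\\*.*$", "", v_call), junction, sep = "|")
}

is_dna <- function(x) grepl("^[ACGT]+$", x)

# productive = in-frame, translation free of stop codons
compute_productive <- function(junction, aa = translate_junction(junction)) {
  !is.na(aa) & !grepl("\\*", aa)
}

# functional = productive plus the conventional C...F/W anchor residues
is_functional <- function(junction, aa, require_anchors = TRUE) {
  if (length(junction) == 0) return(logical(0))
  prod <- compute_productive(junction, aa)
  if (!require_anchors) return(prod)
  prod & startsWith(ifelse(is.na(aa), "", aa), "C") & grepl("[FW]$", ifelse(is.na(aa), "", aa))
}

#' Construct a repertoire sample
#'
#' Bundles a clonotype table with its sample metadata. Rows sharing a clone
#' key are merged by summing counts; `junction_aa` and `productive` are
#' recomputed from the junction when absent.
#'
#' @param clonotypes Data frame with columns `v_call`, `junction`,
#'   `duplicate_count` and optionally `junction_aa`, `productive`,
#'   `sequence_id`.
#' @param sample_id,subject_id Sample and subject labels.
#' @param tissue One of `"PB"`, `"synovium"`.
#' @param subset One of `"naive"`, `"memory"`, `"Th1"`, `"Th17"`, `"Tfh"`,
#'   `"nonTh1Th17Tfh"`, `"memory_all"`, `"cd4_all"`.
#' @param timepoint Ordinal timepoint label (e.g. `"T1"`).
#' @param platform `"bulk-NGS"` or `"single-cell"`; for single-cell samples
#'   `duplicate_count` is a cell count.
#' @param provenance Optional simulator-side read provenance table (oracle
#'   use only); carried as an attribute.
#' @return A `tcr_repertoire`: a tibble of clonotypes (columns `clone_key`,
#'   `v_call`, `junction`, `junction_aa`, `duplicate_count`, `productive`)
#'   with the metadata attached as attributes.
#' @export
repertoire_sample <- function(clonotypes, sample_id, subject_id, tissue,
                              subset, timepoint, platform,
                              provenance = NULL) {
  tissue <- match.arg(tissue, TISSUES)
  subset <- match.arg(subset, SUBSETS)
  platform <- match.arg(platform, PLATFORMS)
  ct <- as_tibble(clonotypes)
  need <- c("v_call", "junction", "duplicate_count")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    abort(paste0("clonotype table lacks mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "clonetrackr_error_missing_columns")
  }
  if (nrow(ct) > 0 && !all(is_dna(ct$junction))) {
    abort("junction contains non-DNA characters (allowed: A, C, G, T)",
          class = "clonetrackr_error_bad_sequence")
  }
  if (any(is.na(ct$duplicate_count)) || any(ct$duplicate_count < 0) ||
      any(ct$duplicate_count != round(ct$duplicate_count))) {
    abort("duplicate_count must be a non-negative integer",
          class = "clonetrackr_error_negative_count")
  }
  ct$duplicate_count <- as.integer(round(ct$duplicate_count))
  if (!"junction_aa" %in% names(ct) || anyNA(ct$junction_aa)) {
    ct$junction_aa <- translate_junction(ct$junction)
  }
  if (!"productive" %in% names(ct)) {
    ct$productive <- compute_productive(ct$junction, ct$junction_aa)
  }
  ct$clone_key <- if (nrow(ct)) make_clone_key(ct$v_call, ct$junction) else character()
  ct <- ct |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(
      v_call = dplyr::first(.data$v_call),
      junction = dplyr::first(.data$junction),
      junction_aa = dplyr::first(.data$junction_aa),
      duplicate_count = sum(.data$duplicate_count),
      productive = dplyr::first(.data$productive),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$duplicate_count), .data$clone_key)
  new_repertoire(ct, sample_id = sample_id, subject_id = subject_id,
                 tissue = tissue, subset = subset, timepoint = timepoint,
                 platform = platform, provenance = provenance)
}

new_repertoire <- function(ct, sample_id, subject_id, tissue, subset,
                           timepoint, platform, provenance = NULL) {
  structure(
    ct,
    class = c("tcr_repertoire", class(as_tibble(ct))),
    sample_id = as.character(sample_id),
    subject_id = as.character(subject_id),
    tissue = tissue, subset = subset,
    timepoint = as.character(timepoint), platform = platform,
    provenance = provenance
  )
}

# rebuild a tcr_repertoire after a dplyr verb stripped its attributes
restore_repertoire <- function(ct, template, provenance = attr(template, "provenance")) {
  new_repertoire(as_tibble(ct),
                 sample_id = attr(template, "sample_id"),
                 subject_id = attr(template, "subject_id"),
                 tissue = attr(template, "tissue"),
                 subset = attr(template, "subset"),
                 timepoint = attr(template, "timepoint"),
                 platform = attr(template, "platform"),
                 provenance = provenance)
}

#' Sample metadata as a one-row tibble
#' @param sample A `tcr_repertoire`.
#' @return One-row tibble: sample_id, subject_id, tissue, subset, timepoint,
#'   platform, n_clonotypes, total_functional.
#' @export
sample_info <- function(sample) {
  tibble(
    sample_id = attr(sample, "sample_id"),
    subject_id = attr(sample, "subject_id"),
    tissue = attr(sample, "tissue"),
    subset = attr(sample, "subset"),
    timepoint = attr(sample, "timepoint"),
    platform = attr(sample, "platform"),
    n_clonotypes = nrow(sample),
    total_functional = total_functional(sample)
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s  subject=%s %s/%s t=%s [%s]\n",
              attr(x, "sample_id"), attr(x, "subject_id"), attr(x, "tissue"),
              attr(x, "subset"), attr(x, "timepoint"), attr(x, "platform")))
  cat(sprintf("  %d clonotypes, %d functional reads\n",
              nrow(x), total_functional(x)))
  print(as_tibble(unclass_keep(x)), ...)
  invisible(x)
}

unclass_keep <- function(x) {
  attr(x, "provenance") <- NULL
  class(x) <- setdiff(class(x), "tcr_repertoire")
  x
}

#' Keep only functional clonotypes
#'
#' Functional means productive (in-frame, no stop codon in the translation)
#' and, by default, carrying the conventional anchor residues: the junction
#' translation starts with cysteine (C) and ends with phenylalanine or
#' tryptophan (F/W). All frequency denominators in the package are totals
#' over functional reads.
#'
#' @param sample A `tcr_repertoire`.
#' @param require_anchors Require the C...F/W anchors (default `TRUE`).
#' @return The filtered `tcr_repertoire`; idempotent.
#' @export
filter_functional <- function(sample, require_anchors = TRUE) {
  stopifnot(inherits(sample, "tcr_repertoire"))
  keep <- is_functional(sample$junction, sample$junction_aa, require_anchors)
  out <- as_tibble(unclass_keep(sample))[keep, , drop = FALSE]
  prov <- attr(sample, "provenance")
  if (!is.null(prov)) prov <- prov[prov$obs_key %in% out$clone_key, , drop = FALSE]
  restore_repertoire(out, sample, provenance = prov)
}

#' Total functional read (or cell) count
#' @param sample A `tcr_repertoire`.
#' @param require_anchors Passed to the functionality rule.
#' @return Integer: sum of counts over functional clonotypes.
#' @export
total_functional <- function(sample, require_anchors = TRUE) {
  keep <- is_functional(sample$junction, sample$junction_aa, require_anchors)
  sum(sample$duplicate_count[keep])
}

assert_same_subject <- function(a, b) {
  if (!identical(attr(a, "subject_id"), attr(b, "subject_id"))) {
    abort(sprintf("samples come from different subjects (%s vs %s)",
                  attr(a, "subject_id"), attr(b, "subject_id")),
          class = "clonetrackr_error_subject_mismatch")
  }
  invisible(TRUE)
}
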