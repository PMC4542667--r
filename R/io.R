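#' Read an AIRR-style rearrangement TSV
#'
#' Reads a tab-separated clonotype table (mandatory columns `v_call`,
#' `junction`, `duplicate_count`; optional `junction_aa`, `productive`,
#' `sequence_id`) and validates it. Rows with identical clone keys are
#' merged by summing counts; `junction_aa` and `productive` are recomputed
#' from the junction when absent. Malformed inputs raise classed conditions:
#' `clonetrackr_error_missing_columns`, `clonetrackr_error_bad_sequence`,
#' `clonetrackr_error_negative_count`.
#'
#' @param path Path to the TSV file.
#' @param sample_id,subject_id,tissue,subset,timepoint,platform Sample
#'   metadata (see [repertoire_sample()]).
#' @return A `tcr_repertoire`.
#' @export
read_repertoire <- function(path, sample_id, subject_id, tissue, subset,
                            timepoint, platform) {
  ct <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("v_call", "junction", "duplicate_count")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    abort(paste0("file ", path, " lacks mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "clonetrackr_error_missing_columns")
  }
  cnt <- suppressWarnings(as.numeric(ct$duplicate_count))
  if (anyNA(cnt)) {
    abort("duplicate_count contains non-numeric values",
          class = "clonetrackr_error_negative_count")
  }
  ct$duplicate_count <- cnt
  if ("productive" %in% names(ct)) {
    ct$productive <- ct$productive %in% c("T", "TRUE", "true", "1")
  }
  repertoire_sample(ct, sample_id = sample_id, subject_id = subject_id,
                    tissue = tissue, subset = subset, timepoint = timepoint,
                    platform = platform)
}

#' Write a repertoire as an AIRR-style rearrangement TSV
#'
#' Columns: sequence_id, v_call, junction, junction_aa, duplicate_count,
#' productive (encoded `T`/`F`). A read-back with [read_repertoire()]
#' reproduces clone keys, counts and productivity exactly.
#'
#' @param sample A `tcr_repertoire`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(sample, path) {
  stopifnot(inherits(sample, "tcr_repertoire"))
  out <- tibble(
    sequence_id = sprintf("%s_%06d", attr(sample, "sample_id"), seq_len(nrow(sample))),
    v_call = sample$v_call,
    junction = sample$junction,
    junction_aa = sample$junction_aa,
    duplicate_count = sample$duplicate_count,
    productive = ifelse(sample$productive, "T", "F")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Columns: sample_id, subject_id, tissue, subset, timepoint, platform,
#' path. Enum columns are validated.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sh <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "subject_id", "tissue", "subset", "timepoint",
            "platform", "path")
  miss <- setdiff(need, names(sh))
  if (length(miss)) {
    abort(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")),
          class = "clonetrackr_error_missing_columns")
  }
  if (!all(sh$tissue %in% TISSUES) || !all(sh$subset %in% SUBSETS) ||
      !all(sh$platform %in% PLATFORMS)) {
    abort("sample sheet contains unknown tissue/subset/platform labels",
          class = "clonetrackr_error_bad_label")
  }
  sh
}

#' Read (and validate) a FACS subset-fraction table
#'
#' Columns: subject_id, timepoint, subset, fraction_of_cd4. Each fraction is
#' the FACS-measured share of the subset within all CD4+ T cells, in
#' \[0, 1\]. When both the memory fraction and the four memory helper-subset
#' fractions (Th1, Th17, Tfh, non-Th1/Th17/Tfh) are present for a
#' subject/timepoint, the helper fractions must not sum to more than the
#' memory fraction (they need not partition it); a violation warns.
#'
#' @param path Path to the TSV.
#' @return A validated tibble (`subset_fractions`).
#' @export
read_subset_fractions <- function(path) {
  fr <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), timepoint = readr::col_character(),
    subset = readr::col_character(), fraction_of_cd4 = readr::col_double()))
  subset_fractions(fr)
}

#' Validate a FACS subset-fraction table given as a data frame
#' @param fr Data frame with columns subject_id, timepoint, subset,
#'   fraction_of_cd4.
#' @return The validated tibble.
#' @export
subset_fractions <- function(fr) {
  fr <- as_tibble(fr)
  need <- c("subject_id", "timepoint", "subset", "fraction_of_cd4")
  miss <- setdiff(need, names(fr))
  if (length(miss)) {
    abort(paste0("fraction table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "clonetrackr_error_missing_columns")
  }
  if (!all(fr$subset %in% SUBSETS)) {
    abort("fraction table contains unknown subset labels",
          class = "clonetrackr_error_bad_label")
  }
  if (any(is.na(fr$fraction_of_cd4)) || any(fr$fraction_of_cd4 < 0) ||
      any(fr$fraction_of_cd4 > 1)) {
    abort("fraction_of_cd4 must lie in [0, 1]",
          class = "clonetrackr_error_bad_fraction")
  }
  helpers <- c("Th1", "Th17", "Tfh", "nonTh1Th17Tfh")
  chk <- fr |>
    dplyr::group_by(.data$subject_id, .data$timepoint) |>
    dplyr::summarise(
      helper_sum = sum(.data$fraction_of_cd4[.data$subset %in% helpers]),
      memory = sum(.data$fraction_of_cd4[.data$subset == "memory"]),
      has_both = any(.data$subset %in% helpers) && any(.data$subset == "memory"),
      .groups = "drop")
  bad <- chk$has_both & chk$helper_sum > chk$memory + 1e-9
  if (any(bad)) {
    warn("memory helper-subset fractions exceed the memory fraction for some subject/timepoint")
  }
  fr$timepoint <- as.character(fr$timepoint)
  fr
}

#' Export a simulated dataset to plain-text files
#'
#' Writes one AIRR-style rearrangement TSV per sample, a sample sheet TSV,
#' and a sidecar truth TSV (clone_key, tissue, subset, timepoint,
#' true_frequency) so the dataset can be re-analysed from files alone.
#'
#' @param truth A `clone_truth`.
#' @param samples List of `tcr_repertoire` objects.
#' @param dir Output directory (created if needed).
#' @return The sample-sheet path, invisibly.
#' @export
export_dataset <- function(truth, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    p <- file.path(dir, paste0(attr(s, "sample_id"), ".tsv"))
    write_repertoire(s, p)
    cbind(sample_info(s)[1:6], tibble(path = p))
  })
  sheet <- dplyr::bind_rows(rows)
  sheet_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(sheet, sheet_path)
  tr <- truth$weights
  names(tr)[names(tr) == "frequency"] <- "true_frequency"
  readr::write_tsv(tr[, c("clone_key", "tissue", "subset", "timepoint",
                          "true_frequency")],
                   file.path(dir, "truth.tsv"))
  invisible(sheet_path)
}
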