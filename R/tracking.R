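#' Classify clones of a single-cell sample as mEC / EC / NEC
#'
#' In a single-cell sample an expanded clone (EC) is a clone observed more
#' than once; a clone observed exactly once is a non-expanded clone (NEC);
#' the most expanded clone (mEC) is the EC with the highest cell count. A
#' tie for the maximum leaves the mEC undesignated (reported via the `tie`
#' attribute) rather than broken arbitrarily.
#'
#' @param sample A `tcr_repertoire` with platform `"single-cell"`.
#' @return Tibble (clone_key, v_call, junction, cells, label) with label in
#'   `{"mEC", "EC", "NEC"}`; attributes `sample_id` and `tie`.
#' @export
classify_single_cell <- function(sample) {
  stopifnot(inherits(sample, "tcr_repertoire"))
  if (attr(sample, "platform") != "single-cell") {
    abort("mEC/EC/NEC classification applies to single-cell samples only",
          class = "clonetrackr_error_platform")
  }
  f <- functional_view(sample)
  assert_nonempty_functional(f)
  out <- tibble(clone_key = f$clone_key, v_call = f$v_call,
                junction = f$junction, cells = f$duplicate_count)
  out$label <- ifelse(out$cells >= 2, "EC", "NEC")
  tie <- FALSE
  if (any(out$label == "EC")) {
    mx <- max(out$cells)
    top <- which(out$cells == mx)
    if (length(top) == 1) out$label[top] <- "mEC" else tie <- TRUE
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$cells), .data$clone_key)
  structure(out, sample_id = attr(sample, "sample_id"), tie = tie,
            class = c("sc_classification", class(out)))
}

#' @export
tidy.sc_classification <- function(x, ...) as_tibble(unclass(x))

sample_is_ec <- function(sample, ec_threshold) {
  f <- functional_view(sample)
  tot <- total_functional(f)
  if (tot == 0) return(setNames(logical(0), character(0)))
  if (attr(sample, "platform") == "single-cell") {
    setNames(f$duplicate_count >= 2, f$clone_key)
  } else {
    setNames(f$duplicate_count / tot > ec_threshold, f$clone_key)
  }
}

#' Track clones across samples of one subject
#'
#' Builds a clone x sample frequency matrix over all samples (timepoints,
#' tissues, subsets, platforms) of a subject; a clone absent from a sample
#' gets frequency 0. A clone is flagged persistent when it meets the
#' platform-appropriate EC criterion (single-cell: observed in more than
#' one cell; bulk: frequency above `ec_threshold`) in at least two
#' timepoints of the same compartment (tissue x subset). Persistent clones
#' receive stable IDs `Ci.j`: `i` indexes the subject (trailing digits of
#' the subject label, else 1), `j` ranks persistent clones by mean
#' frequency across samples, descending — so `j = 1` is the most expanded
#' clone.
#'
#' @param samples List of >= 2 `tcr_repertoire`s, same subject.
#' @param ec_threshold Bulk EC frequency threshold used for the
#'   persistence criterion (default 0.002).
#' @return A `clone_tracking`: `$tracking` long tibble (clone_key,
#'   sample_id, tissue, subset, timepoint, platform, count, frequency, ec)
#'   over the complete clone x sample grid, and `$clones` tibble
#'   (clone_key, n_ec_timepoints, persistent, mean_frequency, clone_id).
#' @export
track_clones <- function(samples, ec_threshold = 0.002) {
  if (length(samples) < 2) {
    abort("clone tracking needs at least 2 samples",
          class = "clonetrackr_error_bad_argument")
  }
  subjects <- unique(vapply(samples, attr, "", "subject_id"))
  if (length(subjects) != 1) {
    abort("samples come from different subjects",
          class = "clonetrackr_error_subject_mismatch")
  }
  long <- dplyr::bind_rows(lapply(samples, function(s) {
    f <- functional_view(s)
    tot <- total_functional(f)
    ec <- sample_is_ec(s, ec_threshold)
    tibble(clone_key = f$clone_key,
           sample_id = attr(s, "sample_id"), tissue = attr(s, "tissue"),
           subset = attr(s, "subset"), timepoint = attr(s, "timepoint"),
           platform = attr(s, "platform"), count = f$duplicate_count,
           frequency = f$duplicate_count / tot,
           ec = unname(ec[f$clone_key]))
  }))
  meta <- unique(long[c("sample_id", "tissue", "subset", "timepoint", "platform")])
  grid <- tidyr::expand_grid(clone_key = unique(long$clone_key),
                             sample_id = meta$sample_id)
  tracking <- grid |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::left_join(long[c("clone_key", "sample_id", "count", "frequency", "ec")],
                     by = c("clone_key", "sample_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  frequency = dplyr::coalesce(.data$frequency, 0),
                  ec = dplyr::coalesce(.data$ec, FALSE))

  clones <- tracking |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(
      n_ec_timepoints = {
        d <- dplyr::pick(dplyr::everything())
        ec_tp <- unique(d[d$ec, c("tissue", "subset", "timepoint")])
        if (nrow(ec_tp)) max(table(paste(ec_tp$tissue, ec_tp$subset))) else 0L
      },
      mean_frequency = mean(.data$frequency),
      .groups = "drop") |>
    dplyr::mutate(persistent = .data$n_ec_timepoints >= 2) |>
    dplyr::arrange(dplyr::desc(.data$mean_frequency), .data$clone_key)
  idx <- sub("^.*?(\\d+)$", "\\1", subjects)
  if (!grepl("^\\d+$", idx)) idx <- "1"
  clones$clone_id <- NA_character_
  pers <- which(clones$persistent)
  clones$clone_id[pers] <- sprintf("C%s.%d", idx, seq_along(pers))
  structure(list(subject_id = subjects, ec_threshold = ec_threshold,
                 tracking = tracking, clones = clones),
            class = "clone_tracking")
}

#' @export
print.clone_tracking <- function(x, ...) {
  cat(sprintf("<clone_tracking> subject=%s: %d clones x %d samples, %d persistent\n",
              x$subject_id, nrow(x$clones),
              length(unique(x$tracking$sample_id)), sum(x$clones$persistent)))
  print(head(x$clones[x$clones$persistent, ], 10), ...)
  invisible(x)
}

#' @export
tidy.clone_tracking <- function(x, ...) {
  dplyr::left_join(x$tracking,
                   x$clones[c("clone_key", "persistent", "clone_id")],
                   by = "clone_key")
}

#' @export
glance.clone_tracking <- function(x, ...) {
  tibble(subject_id = x$subject_id,
         n_clones = nrow(x$clones),
         n_samples = length(unique(x$tracking$sample_id)),
         n_persistent = sum(x$clones$persistent),
         ec_threshold = x$ec_threshold)
}

#' Clone x sample frequency matrix
#' @param x A `clone_tracking`.
#' @return Numeric matrix, rows = clone keys, columns = sample ids.
#' @export
tracking_matrix <- function(x) {
  stopifnot(inherits(x, "clone_tracking"))
  wide <- tidyr::pivot_wider(x$tracking[c("clone_key", "sample_id", "frequency")],
                             names_from = "sample_id",
                             values_from = "frequency", values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$clone_key
  m
}

#' @describeIn track_clones Line plot of persistent-clone frequencies over
#'   timepoints, one line per persistent clone (the longitudinal
#'   repertoire view).
#' @param object A `clone_tracking`.
#' @param ... Unused.
#' @export
autoplot.clone_tracking <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$persistent, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$frequency,
                                   group = .data$clone_id,
                                   colour = .data$clone_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "timepoint", y = "clone frequency",
                  colour = "clone ID") +
    ggplot2::theme_minimal()
}

#' Clones shared between peripheral blood and a tissue sample
#'
#' Returns the clone keys detected (at least one functional read) in the
#' tissue sample and in at least one PB sample of the same subject — the
#' tissue-infiltrating clones whose PB localisation can then be examined
#' with [distribute_clone_set()].
#'
#' @param pb_samples List of PB `tcr_repertoire`s.
#' @param tissue_sample A synovium `tcr_repertoire`, same subject.
#' @return Character vector of clone keys (sorted).
#' @export
intersect_tissues <- function(pb_samples, tissue_sample) {
  if (inherits(pb_samples, "tcr_repertoire")) pb_samples <- list(pb_samples)
  if (attr(tissue_sample, "tissue") != "synovium") {
    abort("tissue_sample must come from the synovium",
          class = "clonetrackr_error_bad_argument")
  }
  for (s in pb_samples) assert_same_subject(s, tissue_sample)
  syn <- functional_view(tissue_sample)
  pb_keys <- unique(unlist(lapply(pb_samples, function(s) functional_view(s)$clone_key)))
  sort(intersect(syn$clone_key, pb_keys))
}
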