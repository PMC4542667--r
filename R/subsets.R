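#' Distribute a set of clones across CD4+ subsets, FACS-size corrected
#'
#' For each subset sample, the in-subset frequency of the target clones
#' (reads of the clones over functional reads of that subset) is multiplied
#' by the FACS-measured fraction of the subset within all CD4+ T cells,
#' correcting for subset size. The corrected contribution is therefore a
#' fraction of all CD4+ T cells. Normalised shares (contributions divided
#' by their sum) are also reported, since sampling dropout means the
#' contributions need not sum to anything fixed.
#'
#' @param keys Character vector of clone keys (non-empty); the per-subset
#'   contribution of a set is the sum of its members' contributions.
#' @param subset_samples List of `tcr_repertoire`s, one per subset, all
#'   from the same subject and timepoint.
#' @param fractions A FACS fraction table (see [subset_fractions()])
#'   containing every sample's subset for that subject/timepoint.
#' @return A `subset_distribution`: tibble with one row per subset —
#'   `subset`, `raw_frequency` (in-subset frequency of the clone set),
#'   `fraction_of_cd4`, `contribution` (their product) and `share`
#'   (normalised contribution; `NA` if all contributions are 0). Attributes
#'   record the keys and subject/timepoint.
#' @export
distribute_clone_set <- function(keys, subset_samples, fractions) {
  if (length(keys) == 0) {
    abort("empty clone key set", class = "clonetrackr_error_empty_keys")
  }
  if (inherits(subset_samples, "tcr_repertoire")) subset_samples <- list(subset_samples)
  subjects <- unique(vapply(subset_samples, attr, "", "subject_id"))
  if (length(subjects) != 1) {
    abort("subset samples come from different subjects",
          class = "clonetrackr_error_subject_mismatch")
  }
  timepoints <- unique(vapply(subset_samples, attr, "", "timepoint"))
  if (length(timepoints) != 1) {
    abort("subset samples come from different timepoints",
          class = "clonetrackr_error_subject_mismatch")
  }
  fractions <- subset_fractions(fractions)
  fr <- fractions[fractions$subject_id == subjects &
                    fractions$timepoint == timepoints, , drop = FALSE]
  rows <- dplyr::bind_rows(lapply(subset_samples, function(s) {
    ss <- attr(s, "subset")
    fcs <- fr$fraction_of_cd4[fr$subset == ss]
    if (length(fcs) == 0) {
      abort(sprintf("subset %s missing from the fraction table for %s/%s",
                    ss, subjects, timepoints),
            class = "clonetrackr_error_missing_fraction")
    }
    raw <- sum(clone_frequency(s, keys))
    tibble(subset = ss, raw_frequency = raw, fraction_of_cd4 = fcs[1],
           contribution = raw * fcs[1])
  }))
  tot <- sum(rows$contribution)
  if (tot > 0) {
    rows$share <- rows$contribution / tot
  } else {
    rows$share <- NA_real_
    warn("clone set undetected in every subset sample; all contributions are zero")
  }
  structure(rows, class = c("subset_distribution", class(rows)),
            keys = keys, subject_id = subjects, timepoint = timepoints)
}

#' Distribute a single clone across CD4+ subsets
#'
#' Single-clone form of [distribute_clone_set()]; used for the mEC
#' localisation analysis.
#'
#' @param key One clone key.
#' @inheritParams distribute_clone_set
#' @return A `subset_distribution` (see [distribute_clone_set()]).
#' @export
distribute_clone <- function(key, subset_samples, fractions) {
  stopifnot(length(key) == 1)
  distribute_clone_set(key, subset_samples, fractions)
}

#' @export
tidy.subset_distribution <- function(x, ...) as_tibble(unclass(x))

#' @export
print.subset_distribution <- function(x, ...) {
  cat(sprintf("<subset_distribution> %d clone(s), subject=%s t=%s\n",
              length(attr(x, "keys")), attr(x, "subject_id"),
              attr(x, "timepoint")))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' @describeIn distribute_clone_set Stacked-bar plot of the normalised
#'   subset shares (or raw contributions with `normalized = FALSE`).
#' @param object A `subset_distribution`.
#' @param normalized Plot shares (default) or raw CD4-scale contributions.
#' @param ... Unused.
#' @export
autoplot.subset_distribution <- function(object, normalized = TRUE, ...) {
  df <- tidy(object)
  df$what <- sprintf("%d clone(s)", length(attr(object, "keys")))
  y <- if (normalized) "share" else "contribution"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data[[y]],
                                   fill = .data$subset)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL,
                  y = if (normalized) "share of detected clone mass"
                      else "fraction of all CD4+ T cells",
                  fill = "subset") +
    ggplot2::theme_minimal()
}
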