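# frequencies are always over functional reads; apply the filter if the
# caller has not (idempotent)
functional_view <- function(sample) {
  if (all(is_functional(sample$junction, sample$junction_aa))) sample
  else filter_functional(sample)
}

assert_nonempty_functional <- function(sample) {
  if (total_functional(sample) == 0) {
    abort(sprintf("sample %s has no functional reads", attr(sample, "sample_id")),
          class = "clonetrackr_error_empty_sample")
  }
  invisible(TRUE)
}

#' Clone frequency within a sample
#'
#' Frequency of a clone = its read (or cell) count divided by the total
#' number of reads with functional CDR3 sequences; 0 for an absent clone.
#'
#' @param sample A `tcr_repertoire`.
#' @param keys Character vector of clone keys (see [make_clone_key()]).
#' @return Numeric vector of frequencies, one per key.
#' @export
clone_frequency <- function(sample, keys) {
  f <- functional_view(sample)
  assert_nonempty_functional(f)
  idx <- match(keys, f$clone_key)
  counts <- ifelse(is.na(idx), 0L, f$duplicate_count[idx])
  counts / total_functional(f)
}

#' Call expanded clones (ECs) at a frequency threshold
#'
#' In bulk sequencing an expanded clone is one whose frequency exceeds a
#' threshold of the functional reads — the study uses 0.2% and 0.1%
#' ("more than" read as strict inequality, so boundary clones are
#' excluded). The EC rate is the cumulative read count of ECs divided by
#' the total number of reads with functional CDR3 sequences.
#'
#' @param sample A `tcr_repertoire` (functional filtering applied if needed).
#' @param threshold Frequency threshold in (0, 1); default 0.002.
#' @return An `ec_call`: list with `threshold`, `ec` (tibble of EC
#'   clonotypes with counts and frequencies), `ec_rate`, `n_ec`,
#'   `total_functional`, `sample_id`. [tidy()] returns the EC table,
#'   [glance()] a one-row summary.
#' @export
call_ecs <- function(sample, threshold = 0.002) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = "clonetrackr_error_bad_argument")
  }
  f <- functional_view(sample)
  assert_nonempty_functional(f)
  tot <- total_functional(f)
  freq <- f$duplicate_count / tot
  is_ec <- freq > threshold
  ec <- as_tibble(unclass_keep(f))[is_ec,
    c("clone_key", "v_call", "junction", "duplicate_count")]
  ec$frequency <- freq[is_ec]
  ec <- dplyr::arrange(ec, dplyr::desc(.data$frequency), .data$clone_key)
  structure(list(sample_id = attr(sample, "sample_id"), threshold = threshold,
                 ec = ec, n_ec = nrow(ec),
                 ec_rate = sum(ec$duplicate_count) / tot,
                 total_functional = tot),
            class = "ec_call")
}

#' @export
print.ec_call <- function(x, ...) {
  cat(sprintf("<ec_call> %s: %d ECs above %.3g%%, EC rate %.4f (of %d functional reads)\n",
              x$sample_id, x$n_ec, 100 * x$threshold, x$ec_rate,
              x$total_functional))
  invisible(x)
}

#' @export
tidy.ec_call <- function(x, ...) x$ec

#' @export
glance.ec_call <- function(x, ...) {
  tibble(sample_id = x$sample_id, threshold = x$threshold, n_ec = x$n_ec,
         ec_rate = x$ec_rate, total_functional = x$total_functional)
}

#' EC rates of one or more samples at several thresholds
#'
#' Convenience wrapper over [call_ecs()] producing a tidy table, one row
#' per sample x threshold.
#'
#' @param samples A `tcr_repertoire` or list of them.
#' @param thresholds Numeric thresholds (default `c(0.002, 0.001)`, the
#'   study's 0.2% and 0.1%).
#' @return Tibble: sample_id, subject_id, tissue, subset, timepoint,
#'   threshold, n_ec, ec_rate.
#' @export
ec_rate_table <- function(samples, thresholds = c(0.002, 0.001)) {
  if (inherits(samples, "tcr_repertoire")) samples <- list(samples)
  dplyr::bind_rows(lapply(samples, function(s) {
    meta <- sample_info(s)[, c("sample_id", "subject_id", "tissue",
                               "subset", "timepoint")]
    dplyr::bind_rows(lapply(thresholds, function(th) {
      g <- glance(call_ecs(s, th))
      cbind(meta, g[, c("threshold", "n_ec", "ec_rate")])
    }))
  }))
}

#' Shared-clone rate between two samples of one subject
#'
#' The shared set is the intersection of clone keys. Each sample gets its
#' own rate: the cumulative functional read count of shared clones divided
#' by that sample's total functional reads — the denominator is per
#' compartment, so the measure is not symmetric.
#'
#' @param sample_a,sample_b `tcr_repertoire`s from the same subject.
#' @return One-row tibble: sample_id_a, sample_id_b, n_shared, rate_a,
#'   rate_b.
#' @export
shared_clone_rate <- function(sample_a, sample_b) {
  assert_same_subject(sample_a, sample_b)
  fa <- functional_view(sample_a); fb <- functional_view(sample_b)
  assert_nonempty_functional(fa); assert_nonempty_functional(fb)
  shared <- intersect(fa$clone_key, fb$clone_key)
  tibble(
    sample_id_a = attr(sample_a, "sample_id"),
    sample_id_b = attr(sample_b, "sample_id"),
    n_shared = length(shared),
    rate_a = sum(fa$duplicate_count[fa$clone_key %in% shared]) / total_functional(fa),
    rate_b = sum(fb$duplicate_count[fb$clone_key %in% shared]) / total_functional(fb)
  )
}

#' Compare a statistic between two groups of samples
#'
#' Two-sided unpaired t-test, classical equal-variance (Student) form by
#' default, Welch via `welch = TRUE`. When both groups are constant the
#' t-test degenerates; the limits are reported explicitly: statistic 0 and
#' p = 1 for equal means, infinite statistic and p = 0 otherwise.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 (e.g. EC
#'   rates of patients vs controls).
#' @param welch Use the Welch (unequal-variance) form.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: estimate (mean difference a - b), statistic, df,
#'   p_value, method, significant.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE, alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values",
          class = "clonetrackr_error_bad_argument")
  }
  est <- mean(values_a) - mean(values_b)
  method <- if (welch) "Welch two-sample t-test" else "Student two-sample t-test"
  res <- tryCatch(
    t.test(values_a, values_b, var.equal = !welch),
    error = function(e) NULL
  )
  if (is.null(res)) {  # zero pooled variance: report the limit
    statistic <- if (abs(est) < .Machine$double.eps) 0 else sign(est) * Inf
    p <- if (statistic == 0) 1 else 0
    df <- length(values_a) + length(values_b) - 2
  } else {
    statistic <- unname(res$statistic); p <- res$p.value
    df <- unname(res$parameter)
  }
  tibble(estimate = est, statistic = statistic, df = df, p_value = p,
         method = method, significant = p < alpha)
}
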