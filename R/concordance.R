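#' Concordance between a single-cell (gold) and a bulk-NGS repertoire
#'
#' For every clone detected in the single-cell sample, its single-cell
#' frequency is paired with its bulk frequency (0 when absent) and the
#' Spearman rank correlation (average ranks for ties) quantifies agreement.
#' Detection sensitivity is the fraction of single-cell clones recovered
#' (count >= 1) by bulk sequencing.
#'
#' @param sc A `tcr_repertoire` with platform `"single-cell"`.
#' @param ngs A `tcr_repertoire` with platform `"bulk-NGS"`, same subject.
#' @return A `concordance_report`: `$pairs` tibble (clone_key, freq_sc,
#'   freq_ngs, detected), `$rho`, `$p_value`, `$sensitivity`,
#'   `$n_matched`. [tidy()] returns the pairs, [glance()] the summary row.
#' @export
concordance <- function(sc, ngs) {
  if (attr(sc, "platform") != "single-cell" || attr(ngs, "platform") != "bulk-NGS") {
    abort("concordance() expects a single-cell gold sample and a bulk-NGS sample",
          class = "clonetrackr_error_platform")
  }
  assert_same_subject(sc, ngs)
  fsc <- functional_view(sc)
  assert_nonempty_functional(fsc)
  fng <- functional_view(ngs)
  assert_nonempty_functional(fng)
  pairs <- tibble(clone_key = fsc$clone_key,
                  freq_sc = fsc$duplicate_count / total_functional(fsc),
                  freq_ngs = clone_frequency(fng, fsc$clone_key))
  pairs$detected <- pairs$freq_ngs > 0
  rho <- p <- NA_real_
  if (nrow(pairs) >= 2 && stats::sd(pairs$freq_sc) > 0 && stats::sd(pairs$freq_ngs) > 0) {
    rho <- cor(pairs$freq_sc, pairs$freq_ngs, method = "spearman")
    p <- suppressWarnings(
      cor.test(pairs$freq_sc, pairs$freq_ngs, method = "spearman",
               exact = FALSE)$p.value)
  }
  structure(list(sc_id = attr(sc, "sample_id"), ngs_id = attr(ngs, "sample_id"),
                 pairs = pairs, rho = rho, p_value = p,
                 sensitivity = mean(pairs$detected),
                 n_matched = sum(pairs$detected)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance> %s vs %s: rho = %.3f (p = %.3g), sensitivity = %.2f (%d/%d)\n",
              x$sc_id, x$ngs_id, x$rho, x$p_value, x$sensitivity,
              x$n_matched, nrow(x$pairs)))
  invisible(x)
}

#' @export
tidy.concordance_report <- function(x, ...) x$pairs

#' @export
glance.concordance_report <- function(x, ...) {
  tibble(sc_id = x$sc_id, ngs_id = x$ngs_id, n_gold = nrow(x$pairs),
         n_matched = x$n_matched, sensitivity = x$sensitivity,
         rho = x$rho, p_value = x$p_value)
}

#' @describeIn concordance Scatter plot of single-cell vs bulk clone
#'   frequencies (log-log, zeros shown at the axis floor).
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- tidy(object)
  floor_ <- min(df$freq_ngs[df$freq_ngs > 0], 1e-6) / 2
  df$freq_ngs_plot <- pmax(df$freq_ngs, floor_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_sc, y = .data$freq_ngs_plot,
                                   colour = .data$detected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "single-cell frequency", y = "bulk-NGS frequency",
                  colour = "detected in bulk") +
    ggplot2::theme_minimal()
}

# Hamming-distance-1 candidate pairs within one (v, length) group, found by
# the masked-signature trick: two equal-length sequences are at distance 1
# iff they share the sequence with the single differing position masked.
hamming1_pairs <- function(seqs) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  idx <- rep(seq_len(n), L)
  sig <- unlist(lapply(seq_len(L), function(p) {
    paste0(substr(seqs, 1, p - 1), ".", substr(seqs, p + 1, L))
  }), use.names = FALSE)
  dup <- sig %in% sig[duplicated(sig)]
  if (!any(dup)) return(NULL)
  grp <- split(idx[dup], sig[dup])
  grp <- grp[lengths(grp) > 1]
  if (!length(grp)) return(NULL)
  pr <- do.call(rbind, lapply(grp, function(v) {
    if (length(v) == 2) matrix(v, 1) else t(combn(v, 2))
  }))
  unique(as.data.frame(pr)) |> setNames(c("i", "j"))
}

#' Absorb likely sequencing-error clonotypes into their parents
#'
#' A simple, evaluable error-correction stage for bulk repertoires: every
#' clonotype pair with the same (allele-stripped) V gene and equal-length
#' CDR3s at Hamming distance 1, where the child's count is at most
#' `ratio_threshold` times the parent's, has the child's reads reassigned
#' to the parent. Parents are considered in descending count order; each
#' child is absorbed at most once, by its largest eligible parent (ties
#' broken by lexicographic CDR3). Chains resolve to the ultimate parent.
#' Total reads are conserved and no new clone keys are created. Correction
#' is intended to run before functional filtering, since an error can
#' toggle productivity.
#'
#' @param sample A bulk-NGS `tcr_repertoire`.
#' @param ratio_threshold Maximum child/parent count ratio in \[0, 1);
#'   0 disables absorption.
#' @return The corrected `tcr_repertoire`; attribute `correction` is a
#'   tibble (child_key, parent_key) of absorptions, and any provenance
#'   attribute is remapped so truth-based evaluation stays valid.
#' @export
correct_errors <- function(sample, ratio_threshold = 0.01) {
  stopifnot(inherits(sample, "tcr_repertoire"))
  if (attr(sample, "platform") == "single-cell") {
    abort("error correction is meaningless at single-cell resolution",
          class = "clonetrackr_error_platform")
  }
  if (!is.numeric(ratio_threshold) || ratio_threshold < 0 || ratio_threshold >= 1) {
    abort("ratio_threshold must lie in [0, 1)",
          class = "clonetrackr_error_bad_argument")
  }
  tb <- as_tibble(unclass_keep(sample))
  tb$v_strip <- sub("\\*.*$", "", tb$v_call)
  tb$len <- nchar(tb$junction)
  tb$row <- seq_len(nrow(tb))

  maps <- list()
  for (g in split(tb[c("row", "junction", "duplicate_count")],
                  paste(tb$v_strip, tb$len))) {
    if (nrow(g) < 2) next
    pr <- hamming1_pairs(g$junction)
    if (is.null(pr)) next
    ci <- g$duplicate_count[pr$i]; cj <- g$duplicate_count[pr$j]
    ji <- g$junction[pr$i]; jj <- g$junction[pr$j]
    # orient: parent = larger count, ties by lexicographically smaller CDR3
    swap <- cj > ci | (cj == ci & jj < ji)
    parent <- ifelse(swap, pr$j, pr$i); child <- ifelse(swap, pr$i, pr$j)
    pc <- g$duplicate_count[parent]; cc <- g$duplicate_count[child]
    ok <- cc <= ratio_threshold * pc & pc > cc
    if (!any(ok)) next
    maps[[length(maps) + 1]] <- tibble(
      child = g$row[child[ok]], parent = g$row[parent[ok]],
      parent_count = pc[ok], parent_junction = g$junction[parent[ok]])
  }
  if (!length(maps)) {
    out <- sample
    attr(out, "correction") <- tibble(child_key = character(),
                                      parent_key = character())
    return(out)
  }
  mp <- dplyr::bind_rows(maps) |>
    dplyr::arrange(.data$child, dplyr::desc(.data$parent_count),
                   .data$parent_junction) |>
    dplyr::distinct(.data$child, .keep_all = TRUE)  # largest eligible parent

  root <- seq_len(nrow(tb))
  root[mp$child] <- mp$parent
  # resolve chains (counts increase strictly along child -> parent, no cycles)
  while (any(root[root] != root)) root <- root[root]

  tb$root <- root
  merged <- tb |>
    dplyr::group_by(.data$root) |>
    dplyr::summarise(duplicate_count = sum(.data$duplicate_count), .groups = "drop")
  out_tb <- tb[match(merged$root, tb$row),
               c("clone_key", "v_call", "junction", "junction_aa", "productive")]
  out_tb$duplicate_count <- merged$duplicate_count
  out_tb <- dplyr::arrange(out_tb, dplyr::desc(.data$duplicate_count),
                           .data$clone_key)

  key_map <- setNames(tb$clone_key[tb$root], tb$clone_key)
  prov <- attr(sample, "provenance")
  if (!is.null(prov)) {
    prov$obs_key <- unname(key_map[prov$obs_key])
    prov <- prov |>
      dplyr::group_by(.data$truth_key, .data$obs_key) |>
      dplyr::summarise(v_call = dplyr::first(.data$v_call),
                       junction = dplyr::first(.data$junction),
                       reads = sum(.data$reads), .groups = "drop")
  }
  out <- restore_repertoire(out_tb[, c("clone_key", "v_call", "junction",
                                       "junction_aa", "duplicate_count",
                                       "productive")],
                            sample, provenance = prov)
  attr(out, "correction") <- tibble(
    child_key = tb$clone_key[mp$child], parent_key = tb$clone_key[mp$parent])
  out
}

#' Evaluate error correction against simulator ground truth
#'
#' Uses the hidden read-provenance channel of simulated samples to score a
#' correction: spurious clonotypes (observed keys matching no true clone)
#' before and after, recall of true clones, the rate of true-clone reads
#' assigned to the wrong true clone, and the Spearman correlation of
#' observed to true clone frequencies before and after. The correlation is
#' taken over the union of observed and true clonotypes (a spurious
#' clonotype has true frequency 0, an undetected true clone observed
#' frequency 0), so it reflects both error removal and abundance recovery.
#'
#' @param before The uncorrected simulated bulk sample.
#' @param after The output of [correct_errors()] on `before`.
#' @param truth The `clone_truth` the sample was drawn from.
#' @return One-row tibble: n_spurious_before, n_spurious_after,
#'   spurious_reduction, recall_before, recall_after,
#'   misassigned_rate_before, misassigned_rate_after, rho_before,
#'   rho_after.
#' @export
evaluate_correction <- function(before, after, truth) {
  prov_b <- attr(before, "provenance"); prov_a <- attr(after, "provenance")
  if (is.null(prov_b) || is.null(prov_a)) {
    abort("read provenance is missing; evaluation needs simulator output",
          class = "clonetrackr_error_no_provenance")
  }
  fr <- truth_frequencies(truth, attr(before, "tissue"),
                          attr(before, "subset"), attr(before, "timepoint"))
  truth_keys <- fr$clone_key
  eval_one <- function(s, prov) {
    total <- sum(s$duplicate_count)
    spurious <- sum(!s$clone_key %in% truth_keys)
    recall <- mean(truth_keys %in% s$clone_key)
    mis <- sum(prov$reads[prov$obs_key %in% truth_keys &
                            prov$obs_key != prov$truth_key]) / total
    all_keys <- union(truth_keys, s$clone_key)
    obs_freq <- s$duplicate_count[match(all_keys, s$clone_key)] / total
    obs_freq[is.na(obs_freq)] <- 0
    true_freq <- fr$frequency[match(all_keys, truth_keys)]
    true_freq[is.na(true_freq)] <- 0
    rho <- if (stats::sd(obs_freq) > 0 && stats::sd(true_freq) > 0) {
      cor(obs_freq, true_freq, method = "spearman")
    } else NA_real_
    list(spurious = spurious, recall = recall, mis = mis, rho = rho)
  }
  b <- eval_one(before, prov_b); a <- eval_one(after, prov_a)
  tibble(
    n_spurious_before = b$spurious, n_spurious_after = a$spurious,
    spurious_reduction = if (b$spurious > 0) 1 - a$spurious / b$spurious else 0,
    recall_before = b$recall, recall_after = a$recall,
    misassigned_rate_before = b$mis, misassigned_rate_after = a$mis,
    rho_before = b$rho, rho_after = a$rho
  )
}
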