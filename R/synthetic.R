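#' Sequencing noise model for bulk repertoire simulation
#'
#' Two noise sources of bulk 5'-RACE TCR sequencing are modelled: PCR
#' amplification bias (a log-normal per-clone amplification factor applied
#' once before read sampling) and per-base substitution sequencing error
#' (i.i.d. over CDR3 positions; no indels). With both at zero the sampler
#' reduces to exact multinomial sampling of the truth.
#'
#' @param substitution_rate Errors per base per read, in \[0, 0.05\].
#' @param pcr_bias_sd Standard deviation of the log-normal per-clone
#'   amplification factor (log scale), >= 0.
#' @param seed Integer seed used by [sample_bulk()] unless overridden.
#' @return A `noise_model` list.
#' @export
noise_model <- function(substitution_rate = 0, pcr_bias_sd = 0, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.05,
            pcr_bias_sd >= 0, is.numeric(seed))
  structure(list(substitution_rate = substitution_rate,
                 pcr_bias_sd = pcr_bias_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# codons without stop codons, used to keep simulated CDR3s productive
NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_junctions <- function(n) {
  lens <- sample(seq(30L, 60L, by = 3L), n, replace = TRUE)
  out <- vapply(lens, function(L) {
    k <- L / 3L - 2L
    paste0("TGT", paste(sample(NONSTOP_CODONS, k, replace = TRUE), collapse = ""),
           sample(c("TTT", "TTC"), 1L))
  }, character(1))
  while (anyDuplicated(out)) {
    i <- which(duplicated(out))
    out[i] <- vapply(lens[i], function(L) {
      k <- L / 3L - 2L
      paste0("TGT", paste(sample(NONSTOP_CODONS, k, replace = TRUE), collapse = ""),
             sample(c("TTT", "TTC"), 1L))
    }, character(1))
  }
  out
}

# scale weights w to total mass M with every element capped at `cap`
# (water-filling); falls back to uniform M/n when the cap is infeasible
fill_to_mass <- function(w, M, cap) {
  n <- length(w)
  if (n * cap < M) {
    warn("too few tail clones to keep them all below the dominant frequencies; tail set uniform")
    return(rep(M / n, n))
  }
  out <- w / sum(w) * M
  repeat {
    over <- out > cap
    if (!any(over)) break
    free <- !over & out < cap
    excess <- sum(out[over] - cap)
    out[over] <- cap
    if (!any(free) || excess <= 0) break
    out[free] <- out[free] + out[free] / sum(out[free]) * excess
  }
  out
}

#' Build a ground-truth clone population
#'
#' Creates a latent clone population shared by a set of compartments
#' (tissue x subset x timepoint). Clone base frequencies follow a discrete
#' power law (Zipf-like) with the given tail exponent. `n_dominant` clones
#' are designated persistent: they sit at the top of every memory-phenotype
#' compartment at every timepoint. Each remaining clone has a "home" subset
#' where it is always present and appears in other compartments with
#' probability `share_prob`, giving the subset-restricted placement and
#' partial inter-compartment sharing seen in real repertoires.
#'
#' @param n_clones Number of distinct clones (> 0).
#' @param n_dominant Number of designated persistent dominant clones
#'   (<= `n_clones`).
#' @param tail_exponent Power-law exponent (> 0) of the clone-size law.
#' @param compartments Data frame with columns `tissue`, `subset`,
#'   `timepoint` naming each compartment to populate.
#' @param seed Integer seed; all randomness in this builder flows from it.
#' @param dominant_freq Optional numeric vector of length `n_dominant`
#'   giving exact true frequencies for the dominant clones in every
#'   memory-phenotype compartment (e.g. `c(0.10, 0.05, 0.02)`); the tail is
#'   scaled to the remaining mass. When `NULL` the dominant clones simply
#'   occupy the top power-law ranks.
#' @param share_prob Probability that a non-dominant clone also appears in
#'   a compartment outside its home subset (default 0.10).
#' @param tail_jitter_sd Log-normal jitter (log-scale sd) applied to
#'   non-dominant clone frequencies per compartment, so timepoints of a
#'   compartment differ realistically (default 0.3).
#' @param subject_id Subject label (default `"RA1"`).
#' @return A `clone_truth` object: `$clones` (clone_key, junction, v_call,
#'   base_frequency, productive), `$weights` (tissue, subset, timepoint,
#'   clone_key, frequency; positive entries only, summing to 1 per
#'   compartment), `$designated_persistent` (clone keys).
#' @export
build_ground_truth <- function(n_clones, n_dominant = 0, tail_exponent = 1.5,
                               compartments, seed, dominant_freq = NULL,
                               share_prob = 0.1, tail_jitter_sd = 0.3,
                               subject_id = "RA1") {
  if (!is.numeric(n_clones) || n_clones < 1) {
    abort("n_clones must be a positive integer", class = "clonetrackr_error_bad_argument")
  }
  if (n_dominant < 0 || n_dominant > n_clones) {
    abort("n_dominant must be in [0, n_clones]", class = "clonetrackr_error_bad_argument")
  }
  if (tail_exponent <= 0) {
    abort("tail_exponent must be > 0", class = "clonetrackr_error_bad_argument")
  }
  compartments <- as_tibble(compartments)
  if (nrow(compartments) == 0 ||
      !all(c("tissue", "subset", "timepoint") %in% names(compartments))) {
    abort("compartments must be a non-empty data frame with tissue, subset, timepoint",
          class = "clonetrackr_error_bad_argument")
  }
  stopifnot(all(compartments$tissue %in% TISSUES),
            all(compartments$subset %in% SUBSETS))
  if (!is.null(dominant_freq)) {
    stopifnot(length(dominant_freq) == n_dominant, all(dominant_freq > 0),
              sum(dominant_freq) < 1)
    dominant_freq <- sort(dominant_freq, decreasing = TRUE)
  }

  withr::with_seed(as.integer(seed), {
    junctions <- random_junctions(n_clones)
    v_call <- sprintf("TRBV%d-%d*0%d",
                      sample(2:30, n_clones, replace = TRUE),
                      sample(1:3, n_clones, replace = TRUE),
                      sample(1:2, n_clones, replace = TRUE))
    clone_key <- make_clone_key(v_call, junctions)
    base <- seq_len(n_clones)^(-tail_exponent)
    base <- base / sum(base)
    clones <- tibble(clone_key = clone_key, junction = junctions,
                     v_call = v_call, base_frequency = base,
                     productive = TRUE)
    dominant <- clone_key[seq_len(n_dominant)]

    subsets_avail <- unique(compartments$subset)
    home <- sample(subsets_avail, n_clones, replace = TRUE)
    any_memory <- any(memory_like(compartments$subset))

    groups <- unique(compartments[c("tissue", "subset")])
    # presence decided once per clone x (tissue, subset), stable over time
    presence <- lapply(seq_len(nrow(groups)), function(g) {
      ss <- groups$subset[g]
      pres <- home == ss | runif(n_clones) < share_prob
      if (n_dominant > 0) {
        pres[seq_len(n_dominant)] <-
          memory_like(ss) || !any_memory  # dominant top every memory compartment
      }
      if (!any(pres)) {
        cand <- setdiff(seq_len(n_clones), seq_len(n_dominant))
        pres[if (length(cand)) cand[1] else 1L] <- TRUE
      }
      pres
    })
    names(presence) <- paste(groups$tissue, groups$subset, sep = "/")

    weights <- dplyr::bind_rows(lapply(seq_len(nrow(compartments)), function(i) {
      ti <- compartments$tissue[i]; ss <- compartments$subset[i]
      tp <- compartments$timepoint[i]
      pres <- presence[[paste(ti, ss, sep = "/")]]
      w <- ifelse(pres, base, 0)
      dom_here <- n_dominant > 0 && pres[1]
      tail_idx <- which(pres)
      if (dom_here) tail_idx <- setdiff(tail_idx, seq_len(n_dominant))
      w[tail_idx] <- w[tail_idx] * exp(rnorm(length(tail_idx), 0, tail_jitter_sd))
      if (dom_here && !is.null(dominant_freq)) {
        tail_mass <- 1 - sum(dominant_freq)
        if (length(tail_idx)) {
          # keep the dominants dominant: tail clones are capped just below
          # the smallest pinned frequency, excess mass redistributed
          cap <- 0.9 * min(dominant_freq)
          w[tail_idx] <- fill_to_mass(w[tail_idx], tail_mass, cap)
        }
        w[seq_len(n_dominant)] <- dominant_freq
        if (!length(tail_idx)) w <- w / sum(w)
      } else {
        w <- w / sum(w)
      }
      keep <- w > 0
      tibble(tissue = ti, subset = ss, timepoint = as.character(tp),
             clone_key = clone_key[keep], frequency = w[keep])
    }))

    structure(list(subject_id = subject_id, clones = clones,
                   weights = weights,
                   designated_persistent = dominant),
              class = "clone_truth")
  })
}

#' @export
print.clone_truth <- function(x, ...) {
  cat(sprintf("<clone_truth> subject=%s: %d clones, %d dominant, %d compartments\n",
              x$subject_id, nrow(x$clones), length(x$designated_persistent),
              nrow(unique(x$weights[c("tissue", "subset", "timepoint")]))))
  invisible(x)
}

#' True clone frequencies of one compartment
#'
#' @param truth A `clone_truth`.
#' @param tissue,subset,timepoint Compartment coordinates.
#' @return Tibble (clone_key, junction, v_call, frequency), positive
#'   frequencies summing to 1.
#' @export
truth_frequencies <- function(truth, tissue, subset, timepoint) {
  stopifnot(inherits(truth, "clone_truth"))
  w <- truth$weights
  w <- w[w$tissue == tissue & w$subset == subset &
           w$timepoint == as.character(timepoint), , drop = FALSE]
  if (nrow(w) == 0) {
    abort(sprintf("compartment %s/%s/%s not present in truth",
                  tissue, subset, timepoint),
          class = "clonetrackr_error_unknown_compartment")
  }
  dplyr::left_join(w[c("clone_key", "frequency")], truth$clones,
                   by = "clone_key")[, c("clone_key", "junction", "v_call", "frequency")]
}

# per-read substitution: mutate k positions of a junction
mutate_read <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Simulate a bulk-NGS repertoire sample
#'
#' Draws `depth` reads from a compartment of the truth: per-clone expected
#' read shares are the true frequencies times a log-normal amplification
#' factor (renormalised), read counts are multinomial, and each read's CDR3
#' is then mutated per base at the substitution rate. Mutated reads found or
#' join observed clonotypes carrying the parent's V call. The true clone of
#' every read is retained in a hidden provenance attribute for oracle use.
#'
#' @param truth A `clone_truth`.
#' @param tissue,subset,timepoint Compartment to sample.
#' @param depth Number of reads (> 0).
#' @param noise A [noise_model()].
#' @param seed Integer seed (defaults to `noise$seed`).
#' @param sample_id Sample label (auto-generated when `NULL`).
#' @return A `tcr_repertoire` with platform `"bulk-NGS"`; attribute
#'   `provenance` is a tibble (truth_key, obs_key, v_call, junction, reads).
#' @export
sample_bulk <- function(truth, tissue, subset, timepoint, depth,
                        noise = noise_model(), seed = noise$seed,
                        sample_id = NULL) {
  stopifnot(inherits(truth, "clone_truth"), inherits(noise, "noise_model"))
  if (!is.numeric(depth) || depth < 1) {
    abort("depth must be a positive integer", class = "clonetrackr_error_bad_argument")
  }
  fr <- truth_frequencies(truth, tissue, subset, timepoint)
  if (is.null(sample_id)) {
    sample_id <- paste(truth$subject_id, tissue, subset, timepoint, "bulk", sep = "_")
  }
  withr::with_seed(as.integer(seed), {
    amp <- fr$frequency * exp(rnorm(nrow(fr), 0, noise$pcr_bias_sd))
    counts <- as.vector(rmultinom(1, size = depth, prob = amp / sum(amp)))
    r <- noise$substitution_rate
    L <- nchar(fr$junction)
    n_err <- if (r > 0) rbinom(nrow(fr), counts, 1 - (1 - r)^L) else integer(nrow(fr))
    clean <- counts - n_err

    rows <- tibble(truth_key = fr$clone_key, v_call = fr$v_call,
                   junction = fr$junction, reads = clean)
    if (sum(n_err) > 0) {
      parent <- rep.int(seq_len(nrow(fr)), n_err)
      # number of substitutions per error read: zero-truncated binomial(L, r)
      kk <- vapply(L[parent], function(Li) {
        p <- stats::dbinom(1:4, Li, r)  # >4 errors per read is negligible
        sample.int(4L, 1L, prob = p)
      }, integer(1))
      mutated <- vapply(seq_along(parent), function(i) {
        mutate_read(fr$junction[parent[i]], kk[i])
      }, character(1))
      rows <- dplyr::bind_rows(rows, tibble(
        truth_key = fr$clone_key[parent], v_call = fr$v_call[parent],
        junction = mutated, reads = 1L))
    }
    rows <- rows[rows$reads > 0, , drop = FALSE]
    prov <- rows |>
      dplyr::group_by(.data$truth_key, .data$v_call, .data$junction) |>
      dplyr::summarise(reads = sum(.data$reads), .groups = "drop") |>
      dplyr::mutate(obs_key = make_clone_key(.data$v_call, .data$junction))
    obs <- prov |>
      dplyr::group_by(.data$v_call, .data$junction) |>
      dplyr::summarise(duplicate_count = sum(.data$reads), .groups = "drop")
    repertoire_sample(obs, sample_id = sample_id, subject_id = truth$subject_id,
                      tissue = tissue, subset = subset, timepoint = timepoint,
                      platform = "bulk-NGS",
                      provenance = prov[, c("truth_key", "obs_key", "v_call",
                                            "junction", "reads")])
  })
}

#' Simulate a single-cell repertoire sample
#'
#' Multinomial draw of `n_cells` cells from the true compartment
#' frequencies, with no sequencing error or amplification bias: single-cell
#' Sanger sequencing is treated as the error-free gold standard. Counts are
#' cell counts.
#'
#' @param truth A `clone_truth`.
#' @param tissue,subset,timepoint Compartment to sample.
#' @param n_cells Number of cells (>= 1); the study design sorts at most
#'   102 cells per sample.
#' @param seed Integer seed.
#' @param sample_id Sample label (auto-generated when `NULL`).
#' @return A `tcr_repertoire` with platform `"single-cell"`.
#' @export
sample_cells <- function(truth, tissue, subset, timepoint, n_cells, seed,
                         sample_id = NULL) {
  stopifnot(inherits(truth, "clone_truth"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("n_cells must be >= 1", class = "clonetrackr_error_bad_argument")
  }
  fr <- truth_frequencies(truth, tissue, subset, timepoint)
  if (is.null(sample_id)) {
    sample_id <- paste(truth$subject_id, tissue, subset, timepoint, "sc", sep = "_")
  }
  withr::with_seed(as.integer(seed), {
    counts <- as.vector(rmultinom(1, size = n_cells, prob = fr$frequency))
    keep <- counts > 0
    obs <- tibble(v_call = fr$v_call[keep], junction = fr$junction[keep],
                  duplicate_count = counts[keep])
    prov <- tibble(truth_key = fr$clone_key[keep],
                   obs_key = fr$clone_key[keep],
                   v_call = fr$v_call[keep], junction = fr$junction[keep],
                   reads = counts[keep])
    repertoire_sample(obs, sample_id = sample_id, subject_id = truth$subject_id,
                      tissue = tissue, subset = subset, timepoint = timepoint,
                      platform = "single-cell", provenance = prov)
  })
}
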