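# toy clonotype builders and independent brute-force oracles used across
# the suite; everything here is deliberately naive

# deterministic functional junction for clone index i: TGT + 8 codons
# encoding i in base 16 + TTT (distinct for i < 16^8, always C...F)
make_junction <- function(i, n_codons = 8) {
  codons <- c("GCA", "GCC", "GCG", "GCT", "TGC", "GAC", "GAA", "TTC",
              "GGA", "CAC", "ATC", "AAA", "CTG", "ATG", "AAC", "CCA")
  digits <- integer(n_codons)
  x <- i
  for (k in seq_len(n_codons)) {
    digits[k] <- x %% 16
    x <- x %/% 16
  }
  paste0("TGT", paste(codons[digits + 1], collapse = ""), "TTT")
}

# repertoire with clone i having counts[i]; clone keys distinct by index
toy_rep <- function(counts, ids = seq_along(counts), sample_id = "S1",
                    subject_id = "RA1", tissue = "PB", subset = "memory",
                    timepoint = "T1", platform = "bulk-NGS") {
  ct <- tibble::tibble(
    v_call = paste0("TRBV", (ids - 1) %% 25 + 2, "-1*01"),
    junction = vapply(ids, make_junction, character(1)),
    duplicate_count = counts
  )
  repertoire_sample(ct, sample_id = sample_id, subject_id = subject_id,
                    tissue = tissue, subset = subset, timepoint = timepoint,
                    platform = platform)
}

sc_rep <- function(counts, ids = seq_along(counts), timepoint = "T1",
                   sample_id = paste0("SC_", timepoint), ...) {
  toy_rep(as.integer(counts), ids = ids, platform = "single-cell",
          timepoint = timepoint, sample_id = sample_id, ...)
}

toy_key <- function(i) {
  make_clone_key(paste0("TRBV", (i - 1) %% 25 + 2, "-1*01"), make_junction(i))
}

# brute-force EC rate: literal sort-and-sum over integer counts
oracle_ec_rate <- function(counts, threshold) {
  tot <- sum(counts)
  sum(counts[counts / tot > threshold]) / tot
}

oracle_shared_rates <- function(ids_a, counts_a, ids_b, counts_b) {
  shared <- intersect(ids_a, ids_b)
  c(sum(counts_a[ids_a %in% shared]) / sum(counts_a),
    sum(counts_b[ids_b %in% shared]) / sum(counts_b))
}

# brute-force FACS-corrected distribution: loop clones x subsets
oracle_distribution <- function(key_ids, subset_tables, fracs) {
  # subset_tables: named list subset -> list(ids, counts); fracs named vector
  contrib <- setNames(numeric(length(subset_tables)), names(subset_tables))
  for (ss in names(subset_tables)) {
    tab <- subset_tables[[ss]]
    tot <- sum(tab$counts)
    for (i in key_ids) {
      cnt <- if (i %in% tab$ids) tab$counts[match(i, tab$ids)] else 0
      contrib[ss] <- contrib[ss] + cnt / tot * fracs[[ss]]
    }
  }
  contrib
}

# all count multisets of at most `max_cells` cells over at most `max_clones`
# clones (partitions with bounded part count), as a list of integer vectors
count_multisets <- function(max_cells, max_clones) {
  out <- list()
  gen <- function(remaining, max_part, acc) {
    if (length(acc) > 0) out[[length(out) + 1]] <<- acc
    if (remaining == 0 || length(acc) == max_clones) return()
    for (p in seq_len(min(remaining, max_part))) {
      gen(remaining - p, p, c(acc, p))
    }
  }
  for (n in seq_len(max_cells)) gen(n, n, integer(0))
  unique(out)
}

study_compartments <- function() {
  rbind(
    expand.grid(tissue = "PB",
                subset = c("naive", "memory", "Th1", "Th17", "Tfh",
                           "nonTh1Th17Tfh"),
                timepoint = c("T1", "T2", "T3"),
                stringsAsFactors = FALSE),
    data.frame(tissue = "synovium", subset = "cd4_all", timepoint = "T1")
  )
}
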