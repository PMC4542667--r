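one_comp <- data.frame(tissue = "PB", subset = "memory", timepoint = "T1")

test_that("ground truth normalises, places dominants, and is reproducible", {
  # single clone: normalisation forces frequency 1
  tr1 <- build_ground_truth(1, 0, 1.5, one_comp, seed = 1)
  expect_equal(truth_frequencies(tr1, "PB", "memory", "T1")$frequency, 1)

  # per-compartment frequencies sum to 1; same seed is bit-identical
  comp <- study_compartments()
  tr <- build_ground_truth(1000, 0, 1.5, comp, seed = 7)
  sums <- tapply(tr$weights$frequency,
                 paste(tr$weights$tissue, tr$weights$subset, tr$weights$timepoint),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  tr_again <- build_ground_truth(1000, 0, 1.5, comp, seed = 7)
  top10 <- function(x) sum(sort(truth_frequencies(x, "PB", "memory", "T1")$frequency,
                                decreasing = TRUE)[1:10])
  expect_identical(top10(tr), top10(tr_again))

  # every designated clone is present at every timepoint of the memory compartment
  trd <- build_ground_truth(1000, 3, 1.5, comp, seed = 11)
  for (tp in c("T1", "T2", "T3")) {
    f <- truth_frequencies(trd, "PB", "memory", tp)
    expect_true(all(trd$designated_persistent %in% f$clone_key))
    expect_true(all(f$frequency[match(trd$designated_persistent, f$clone_key)] > 0))
  }
  # pinned dominant frequencies stay on top of the memory compartment
  trp <- build_ground_truth(1000, 3, 1.5, comp, seed = 11,
                            dominant_freq = c(0.10, 0.05, 0.02))
  f <- truth_frequencies(trp, "PB", "memory", "T2")
  dom <- f$frequency[match(trp$designated_persistent, f$clone_key)]
  expect_equal(sort(dom, decreasing = TRUE), c(0.10, 0.05, 0.02))
  expect_lte(max(f$frequency[!f$clone_key %in% trp$designated_persistent]), 0.02)

  # simulated junctions are in-frame C...F by construction
  expect_true(all(nchar(tr$clones$junction) %% 3 == 0))
  aa <- translate_junction(tr$clones$junction)
  expect_true(all(startsWith(aa, "C") & endsWith(aa, "F")))
  expect_false(any(grepl("\\*", aa)))

  expect_error(build_ground_truth(0, 0, 1.5, one_comp, seed = 1),
               class = "clonetrackr_error_bad_argument")
  expect_error(build_ground_truth(10, 0, -1, one_comp, seed = 1),
               class = "clonetrackr_error_bad_argument")
  expect_error(build_ground_truth(10, 0, 1.5, one_comp[0, ], seed = 1),
               class = "clonetrackr_error_bad_argument")
})

test_that("noise-free bulk sampling is exact multinomial and conserves reads", {
  tr1 <- build_ground_truth(1, 0, 1.5, one_comp, seed = 1)
  b1 <- sample_bulk(tr1, "PB", "memory", "T1", 1e6, noise_model(seed = 5))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$duplicate_count, 1000000L)

  tr <- build_ground_truth(200, 0, 1.5, one_comp, seed = 3)
  b <- sample_bulk(tr, "PB", "memory", "T1", 12345,
                   noise_model(0.002, 0.4, seed = 9))
  expect_equal(sum(b$duplicate_count), 12345L)
  # hidden provenance channel partitions the reads
  prov <- attr(b, "provenance")
  expect_equal(sum(prov$reads), 12345L)
  by_obs <- tapply(prov$reads, prov$obs_key, sum)
  expect_equal(as.vector(by_obs[b$clone_key]), b$duplicate_count)
  # determinism under the same seed
  b2 <- sample_bulk(tr, "PB", "memory", "T1", 12345,
                    noise_model(0.002, 0.4, seed = 9))
  expect_identical(as.data.frame(b), as.data.frame(b2))

  expect_error(sample_bulk(tr, "PB", "naive", "T1", 100, noise_model()),
               class = "clonetrackr_error_unknown_compartment")
  expect_error(sample_bulk(tr, "PB", "memory", "T1", 0, noise_model()),
               class = "clonetrackr_error_bad_argument")
})

test_that("the fraction of error-bearing reads matches the binomial closed form", {
  # one clone of CDR3 length 45, substitution rate 1e-3:
  # P(read has >= 1 error) = 1 - (1 - 0.001)^45 ~ 4.4%
  tr <- build_ground_truth(1, 0, 1.5, one_comp, seed = 1)
  stopifnot(nchar(tr$clones$junction) >= 30)
  L <- nchar(tr$clones$junction[1])
  p_err <- 1 - (1 - 0.001)^L
  depth <- 1e5
  b <- sample_bulk(tr, "PB", "memory", "T1", depth, noise_model(0.001, 0, seed = 21))
  err_reads <- depth - b$duplicate_count[b$junction == tr$clones$junction[1]]
  band <- 3 * sqrt(depth * p_err * (1 - p_err))
  expect_lt(abs(err_reads - depth * p_err), band)
  # error reads inherit the parent V call
  expect_true(all(b$v_call == tr$clones$v_call[1]))
})

test_that("single-cell sampling matches binomial moments and needs >= 1 cell", {
  comp <- one_comp
  tr <- build_ground_truth(2, 0, 1.5, comp, seed = 2)
  # force a two-clone truth at 0.9/0.1 to check the mean cell count
  tr$weights$frequency <- c(0.9, 0.1)[match(tr$weights$clone_key, tr$clones$clone_key)]
  key <- tr$clones$clone_key[2]
  counts <- vapply(1:1000, function(s) {
    sc <- sample_cells(tr, "PB", "memory", "T1", 102, seed = s)
    i <- match(key, sc$clone_key)
    if (is.na(i)) 0L else sc$duplicate_count[i]
  }, integer(1))
  expect_true(all(counts >= 0 & counts <= 102))
  sd_mean <- sqrt(102 * 0.1 * 0.9 / 1000)
  expect_lt(abs(mean(counts) - 10.2), 3 * sd_mean)

  sc1 <- sample_cells(tr, "PB", "memory", "T1", 102, seed = 1)
  expect_equal(sum(sc1$duplicate_count), 102L)
  expect_error(sample_cells(tr, "PB", "memory", "T1", 0, seed = 1),
               class = "clonetrackr_error_bad_argument")
  tr1 <- build_ground_truth(1, 0, 1.5, comp, seed = 4)
  one <- sample_cells(tr1, "PB", "memory", "T1", 102, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$duplicate_count, 102L)
})

test_that("with noise off, observed frequencies converge to truth with depth", {
  tr <- build_ground_truth(300, 0, 1.5, one_comp, seed = 13)
  truth <- truth_frequencies(tr, "PB", "memory", "T1")
  tv <- function(depth, seed) {
    b <- sample_bulk(tr, "PB", "memory", "T1", depth, noise_model(seed = seed))
    obs <- b$duplicate_count[match(truth$clone_key, b$clone_key)] / depth
    obs[is.na(obs)] <- 0
    sum(abs(obs - truth$frequency)) / 2
  }
  tv_lo <- mean(vapply(1:20, function(s) tv(1e3, s), numeric(1)))
  tv_hi <- mean(vapply(1:20, function(s) tv(1e5, 100 + s), numeric(1)))
  expect_lt(tv_hi, tv_lo)
})
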