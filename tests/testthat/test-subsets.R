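frac_tbl <- function(th1 = 0.10, th17 = 0.05, tfh = 0.07, nonth = 0.40) {
  data.frame(subject_id = "RA1", timepoint = "T1",
             subset = c("Th1", "Th17", "Tfh", "nonTh1Th17Tfh"),
             fraction_of_cd4 = c(th1, th17, tfh, nonth))
}

test_that("the corrected contribution is frequency times FACS fraction", {
  # clone 1 at in-subset frequency 0.01 in a subset occupying 0.20 of CD4
  th1 <- toy_rep(c(1L, 99L), ids = 1:2, subset = "Th1", sample_id = "A")
  fr <- frac_tbl(th1 = 0.20)
  d <- distribute_clone(toy_key(1), list(th1), fr)
  expect_equal(d$contribution[d$subset == "Th1"], 0.01 * 0.20)
  expect_equal(d$share[d$subset == "Th1"], 1)  # only subset where it appears

  # hand product: 0.04 x 0.10 and 0.01 x 0.40 -> equal contributions
  th1b <- toy_rep(c(4L, 96L), ids = 1:2, subset = "Th1", sample_id = "A")
  nonth <- toy_rep(c(1L, 99L), ids = c(1, 3), subset = "nonTh1Th17Tfh",
                   sample_id = "B")
  d2 <- distribute_clone(toy_key(1), list(th1b, nonth), frac_tbl())
  expect_equal(d2$contribution[d2$subset == "Th1"], 0.004)
  expect_equal(d2$contribution[d2$subset == "nonTh1Th17Tfh"], 0.004)
  expect_equal(d2$share, c(0.5, 0.5))
})

test_that("clone-set distribution is additive and matches per-clone brute force", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      subs <- c("Th1", "Th17", "Tfh", "nonTh1Th17Tfh")
      samples <- lapply(seq_along(subs), function(i) {
        ids <- sample(1:60, 25)
        toy_rep(as.integer(sample(1:200, 25, replace = TRUE)), ids = ids,
                subset = subs[i], sample_id = paste0("S", i))
      })
      keys_id <- sample(1:60, 50)
      keys <- vapply(keys_id, toy_key, character(1))
      d <- distribute_clone_set(keys, samples, frac_tbl())

      # oracle: entrywise sum of single-clone distributions
      per_clone <- lapply(keys, function(k) {
        suppressWarnings(distribute_clone(k, samples, frac_tbl()))
      })
      summed <- Reduce(`+`, lapply(per_clone, function(x) x$contribution))
      expect_equal(d$contribution, summed, tolerance = 1e-12)

      # independent loop-based oracle
      tabs <- lapply(samples, function(s) {
        list(ids = s$clone_key, counts = s$duplicate_count)
      })
      names(tabs) <- subs
      fr <- frac_tbl(); fracs <- setNames(fr$fraction_of_cd4, fr$subset)
      expect_equal(setNames(d$contribution, d$subset),
                   oracle_distribution(keys, tabs, fracs)[d$subset])

      # normalised shares sum to 1
      if (sum(d$contribution) > 0) {
        expect_equal(sum(d$share), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("doubling one subset's FACS fraction doubles only that contribution", {
  subs <- lapply(c("Th1", "nonTh1Th17Tfh"), function(ss) {
    toy_rep(c(7L, 13L, 80L), ids = 1:3, subset = ss, sample_id = ss)
  })
  d1 <- distribute_clone_set(vapply(1:2, toy_key, ""), subs, frac_tbl(th1 = 0.10))
  d2 <- distribute_clone_set(vapply(1:2, toy_key, ""), subs, frac_tbl(th1 = 0.20))
  expect_equal(d2$contribution[d2$subset == "Th1"],
               2 * d1$contribution[d1$subset == "Th1"])
  expect_equal(d2$contribution[d2$subset == "nonTh1Th17Tfh"],
               d1$contribution[d1$subset == "nonTh1Th17Tfh"])
})

test_that("degenerate distribution inputs are handled as declared", {
  th1 <- toy_rep(c(5L, 5L), ids = 1:2, subset = "Th1")
  expect_error(distribute_clone_set(character(0), list(th1), frac_tbl()),
               class = "clonetrackr_error_empty_keys")
  # subset absent from the fraction table
  tfh <- toy_rep(c(5L, 5L), ids = 1:2, subset = "Tfh")
  fr <- frac_tbl()[frac_tbl()$subset != "Tfh", ]
  expect_error(distribute_clone(toy_key(1), list(tfh), fr),
               class = "clonetrackr_error_missing_fraction")
  # mismatched subjects
  other <- toy_rep(c(5L, 5L), ids = 1:2, subset = "Th17", subject_id = "RA2")
  expect_error(distribute_clone(toy_key(1), list(th1, other), frac_tbl()),
               class = "clonetrackr_error_subject_mismatch")
  # clone undetected everywhere: all-zero distribution with a warning
  expect_warning(d <- distribute_clone(toy_key(999), list(th1), frac_tbl()),
                 "undetected")
  expect_equal(d$contribution, 0)
  expect_true(is.na(d$share))
})
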