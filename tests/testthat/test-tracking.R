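test_that("single-cell classification applies the mEC/EC/NEC definitions", {
  cl <- classify_single_cell(sc_rep(c(8, 2, 1, 1)))
  expect_equal(setNames(cl$label, cl$clone_key)[vapply(1:4, toy_key, "")],
               setNames(c("mEC", "EC", "NEC", "NEC"), vapply(1:4, toy_key, "")))

  all_single <- classify_single_cell(sc_rep(c(1, 1, 1)))
  expect_true(all(all_single$label == "NEC"))
  expect_false(any(all_single$label == "mEC"))

  tie <- classify_single_cell(sc_rep(c(5, 5, 1)))
  expect_equal(sort(tie$label), c("EC", "EC", "NEC"))
  expect_true(attr(tie, "tie"))
  expect_false(any(tie$label == "mEC"))

  # labels partition the clones; at most one mEC
  expect_equal(nrow(cl), length(unique(cl$clone_key)))
  expect_lte(sum(cl$label == "mEC"), 1)

  expect_error(classify_single_cell(toy_rep(c(5L, 1L))),
               class = "clonetrackr_error_platform")
  expect_error(classify_single_cell(sc_rep(integer(0))),
               class = "clonetrackr_error_empty_sample")
})

test_that("tracking flags persistence from repeated EC status and assigns Ci.j", {
  # three clones seen >= 2 cells at both timepoints, tails seen once each
  s1 <- sc_rep(c(10, 5, 2, 1, 1), ids = 1:5, timepoint = "T1")
  s2 <- sc_rep(c(11, 5, 2, 1), ids = c(1, 2, 3, 6), timepoint = "T2")
  trk <- track_clones(list(s1, s2))
  cl <- trk$clones
  expect_equal(sort(cl$clone_key[cl$persistent]), sort(vapply(1:3, toy_key, "")))
  # IDs ordered by mean frequency descending: 1 > 2 > 3
  expect_equal(cl$clone_id[match(vapply(1:3, toy_key, ""), cl$clone_key)],
               c("C1.1", "C1.2", "C1.3"))
  # clone 4 present at one timepoint only: kept, with a zero cell elsewhere
  m <- tracking_matrix(trk)
  expect_equal(unname(m[toy_key(4), "SC_T2"]), 0)
  expect_false(cl$persistent[cl$clone_key == toy_key(4)])
  # frequencies per sample sum to 1 over detected clones
  expect_equal(unname(colSums(m)), c(1, 1), tolerance = 1e-12)

  # subject index comes from the subject label
  s1b <- sc_rep(c(9, 3), ids = 1:2, timepoint = "T1", subject_id = "RA2")
  s2b <- sc_rep(c(8, 3), ids = 1:2, timepoint = "T2", subject_id = "RA2")
  expect_equal(track_clones(list(s1b, s2b))$clones$clone_id[1], "C2.1")

  expect_error(track_clones(list(s1)), class = "clonetrackr_error_bad_argument")
  expect_error(track_clones(list(s1, sc_rep(c(3, 3), subject_id = "HC1"))),
               class = "clonetrackr_error_subject_mismatch")
})

test_that("bulk persistence uses the frequency-threshold EC definition", {
  b1 <- toy_rep(c(30L, 3L, 967L), ids = 1:3, timepoint = "T1", sample_id = "B1")
  b2 <- toy_rep(c(25L, 1L, 974L), ids = 1:3, timepoint = "T2", sample_id = "B2")
  trk <- track_clones(list(b1, b2), ec_threshold = 0.002)
  cl <- trk$clones
  expect_true(cl$persistent[cl$clone_key == toy_key(1)])   # 3% and 2.5%
  expect_false(cl$persistent[cl$clone_key == toy_key(2)])  # 0.3% then 0.1%
})

test_that("designated clones flagged persistent in >= 95% of seeds when truly >= 5%", {
  comp <- data.frame(tissue = "PB", subset = "memory",
                     timepoint = c("T1", "T2", "T3"))
  hits <- vapply(1:60, function(s) {
    tr <- build_ground_truth(500, 2, 1.5, comp, seed = 3000 + s,
                             dominant_freq = c(0.10, 0.05))
    scs <- lapply(1:3, function(i) {
      sample_cells(tr, "PB", "memory", paste0("T", i), 102, seed = 100 * s + i)
    })
    cl <- track_clones(scs)$clones
    all(cl$persistent[match(tr$designated_persistent, cl$clone_key)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("tissue intersection returns clones detected in synovium and PB", {
  pb <- toy_rep(c(10L, 5L, 2L), ids = 1:3)
  syn_disjoint <- toy_rep(c(4L, 4L), ids = 4:5, tissue = "synovium",
                          sample_id = "SYN")
  expect_equal(intersect_tissues(list(pb), syn_disjoint), character(0))

  syn_subset <- toy_rep(c(4L, 4L), ids = c(1, 3), tissue = "synovium",
                        sample_id = "SYN")
  expect_equal(intersect_tissues(list(pb), syn_subset),
               sort(vapply(c(1, 3), toy_key, "")))

  expect_error(intersect_tissues(list(pb), toy_rep(5L, tissue = "PB")),
               class = "clonetrackr_error_bad_argument")
  expect_error(intersect_tissues(list(pb),
                                 toy_rep(5L, tissue = "synovium",
                                         subject_id = "RA9")),
               class = "clonetrackr_error_subject_mismatch")
})

test_that("deep noise-free sampling recovers exactly the clones seeded in both tissues", {
  comp <- rbind(data.frame(tissue = "PB", subset = "memory", timepoint = "T1"),
                data.frame(tissue = "synovium", subset = "cd4_all", timepoint = "T1"))
  tr <- build_ground_truth(300, 5, 1.5, comp, seed = 99, share_prob = 0)
  pb <- sample_bulk(tr, "PB", "memory", "T1", 2e4, noise_model(seed = 1))
  syn <- sample_bulk(tr, "synovium", "cd4_all", "T1", 2e4, noise_model(seed = 2))
  # with share_prob = 0 only the designated dominants live in both tissues
  expect_equal(intersect_tissues(list(pb), syn),
               sort(tr$designated_persistent))
})
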