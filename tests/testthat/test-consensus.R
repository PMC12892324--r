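test_that("min-max normalization maps bounds to 0/1 and never clips", {
  b <- norm_bounds(-2.80, 12.073)
  expect_equal(normalize_minmax(-2.80, b), 0)
  expect_equal(normalize_minmax(12.073, b), 1)
  # hand arithmetic: (6.52 + 2.80) / 14.873
  expect_equal(normalize_minmax(6.52, b), 9.32 / 14.873, tolerance = 1e-12)
  # out-of-bound values stay out of [0, 1]
  expect_lt(normalize_minmax(-5, b), 0)
  expect_gt(normalize_minmax(20, b), 1)
  expect_error(norm_bounds(1, 1), "exceed")
})

test_that("consensus scores fuse the channels and respect monotonicity", {
  expect_equal(consensus_score(-12.073, 9), 2.0)
  expect_equal(consensus_score(2.80, 0), 0.0)
  expect_equal(consensus_score(-6.52, 5), 9.32 / 14.873 + 5 / 9,
               tolerance = 1e-12)
  # strictly decreasing in raw docking score, increasing in votes
  d <- seq(-10, 2, length.out = 25)
  expect_true(all(diff(consensus_score(d, 4)) < 0))
  expect_true(all(diff(consensus_score(-6, 0:9)) > 0))
  expect_true(is.na(consensus_score(NA, 5)))
})

test_that("classification metrics match the brute-force oracle", {
  set.seed(77)
  for (rep in 1:50) {
    v <- sample(0:20, 4, replace = TRUE)
    if (sum(v) == 0) next
    m <- classification_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    o <- oracle_metrics(v[1], v[2], v[3], v[4])
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], info = nm)
  }
  perfect <- classification_metrics(confusion_counts(5, 5, 0, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$ba, 1)
  expect_equal(perfect$f1, 1)
  # degenerate denominators return sentinels with flags
  deg <- classification_metrics(confusion_counts(0, 5, 0, 5))
  expect_equal(deg$precision, 0)
  expect_equal(deg$mcc, 0)
  expect_true("mcc_zero_denominator" %in% deg$flags)
})

test_that("ROC AUC is concordance with midranks and transform-invariant", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(exp(scores / 2), labels), roc_auc(scores, labels))
  }
  expect_warning(roc_auc(c(1, 2, NA, 4), c(1, 0, 1, 0)), "1 compound")
  expect_warning(a <- roc_auc(1:4, rep(1, 4)), "one class")
  expect_true(is.na(a))
})

test_that("KDE threshold finds the symmetric crossing and falls back cleanly", {
  set.seed(123)
  act <- rnorm(300, 1, 0.1)
  inact <- rnorm(300, 0, 0.1)
  thr <- kde_threshold(act, inact)
  expect_equal(as.numeric(thr), 0.5, tolerance = 0.05)
  expect_equal(attr(thr, "method"), "kde_crossing")

  # identical class distributions: no meaningful crossing, fallback + warning
  same <- rnorm(50)
  expect_warning(thr2 <- kde_threshold(same, same), "falling back")
  expect_equal(attr(thr2, "method"), "mcc_fallback")

  expect_error(kde_threshold(1:3, 1:10), "at least 5")

  # docking-style orientation (actives more negative) is handled
  thr3 <- kde_threshold(rnorm(200, -8, 0.5), rnorm(200, -5, 0.5))
  expect_equal(as.numeric(thr3), -6.5, tolerance = 0.3)
  expect_equal(attr(thr3, "orientation"), -1)
})

test_that("channel imputation applies its rules in order", {
  dup <- data.frame(removed_id = c("salt_b", "iso_d"),
                    kept_id = c("parent_a", "parent_c"))
  dock <- data.frame(id = c("parent_a", "parent_c", "undock_e", "plain_f"),
                     dock_score = c(-7.1, -5.0, NA, 2.78),
                     docked = c(TRUE, TRUE, FALSE, TRUE))
  votes <- data.frame(id = c("parent_a", "parent_c", "undock_e", "plain_f"),
                      votes = c(8, 2, 5, 1))
  out <- impute_missing(c("salt_b", "iso_d", "undock_e", "plain_f", "metal_g"),
                        dup, dock, votes)
  # salt inherits both channels from its surviving parent
  expect_equal(out$dock_score[out$id == "salt_b"], -7.1)
  expect_equal(out$votes[out$id == "salt_b"], 8)
  expect_match(out$note[out$id == "salt_b"], "dock_from_parent_a")
  # stereoisomer inherits the ML votes
  expect_equal(out$votes[out$id == "iso_d"], 2)
  # attempted-but-undocked: worst observed (2.78) + 0.02 = 2.8
  expect_equal(out$dock_score[out$id == "undock_e"], 2.8)
  expect_match(out$note[out$id == "undock_e"], "undocked_penalty")
  # excluded everywhere: both channels stay missing -> not_available
  expect_true(is.na(out$dock_score[out$id == "metal_g"]))
  res <- classify_consensus(out)
  expect_equal(res$predicted_label[res$id == "metal_g"], "not_available")
  expect_true(is.na(res$consensus[res$id == "metal_g"]))

  cyc <- data.frame(removed_id = c("a", "b"), kept_id = c("b", "a"))
  expect_error(impute_missing("a", cyc, dock, votes), "cyclic")
})

test_that("consensus classification uses a strict threshold", {
  ch <- data.frame(id = c("at", "above", "below"),
                   dock_score = c(-6.52, -12.073, 2.80),
                   votes = c(5, 9, 0))
  # a compound sitting exactly on the threshold is NOT called active
  thr_exact <- consensus_score(-6.52, 5)
  res <- classify_consensus(ch, threshold = thr_exact)
  expect_equal(res$predicted_label, c("inactive", "active", "inactive"))
  expect_equal(res$consensus[2], 2.0)
  res2 <- classify_consensus(ch, threshold = thr_exact - 1e-9)
  expect_equal(res2$predicted_label[1], "active")
})

test_that("pChEMBL labeling is inclusive at the threshold", {
  expect_equal(pchembl_label(6.0, 6), "active")
  expect_equal(pchembl_label(5.99, 6), "inactive")
  expect_equal(pchembl_label(6.5, 7), "inactive")
  expect_equal(pchembl_label(c(5, 6, 7), 6),
               c("inactive", "active", "active"))
  expect_error(pchembl_label(NA_real_), "finite")
})
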