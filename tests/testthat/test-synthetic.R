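test_that("synthetic spec validates its fields", {
  expect_error(synthetic_spec(n_active = 0), "n_active")
  expect_error(synthetic_spec(n_inactive = -3), "n_inactive")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  s <- synthetic_spec(7, 88, seed = 3)
  expect_s3_class(s, "synthetic_spec")
  # the screening regime this emulates: ~1:12.5 imbalance
  expect_equal(s$n_inactive / s$n_active, 12.57, tolerance = 0.01)
})

test_that("generation is bit-identical under a fixed spec + seed", {
  s <- synthetic_spec(10, 50, n_features = 5, seed = 11)
  a <- gen_descriptors(s)
  b <- gen_descriptors(s)
  expect_identical(a$features, b$features)
  expect_identical(gen_docking_scores(attr(a, "labels"), s),
                   gen_docking_scores(attr(b, "labels"), s))
  # different seed changes the draw
  s2 <- synthetic_spec(10, 50, n_features = 5, seed = 12)
  expect_false(identical(gen_descriptors(s2)$features, a$features))
})

test_that("descriptor generator plants the stated class structure", {
  s <- synthetic_spec(400, 400, n_features = 8, effect_size = 2, seed = 5)
  dm <- gen_descriptors(s)
  lab <- attr(dm, "labels")
  expect_equal(dim(dm$features), c(800, 8))
  expect_equal(sum(lab), 400)
  shift <- colMeans(dm$features[lab == 1, ]) - colMeans(dm$features[lab == 0, ])
  expect_equal(mean(shift), 2, tolerance = 0.15)
  bin <- gen_descriptors(s, binarize = TRUE)
  expect_true(all(bin$features %in% c(0, 1)))
  expect_identical(bin$kind, "binary_fingerprint")
})

test_that("no-signal data gives chance-level AUC; strong signal is separable", {
  s0 <- synthetic_spec(1000, 1000, n_features = 10, effect_size = 0, seed = 8)
  dm0 <- gen_descriptors(s0)
  auc0 <- roc_auc(rowMeans(dm0$features), attr(dm0, "labels"))
  # null AUC has SD ~ 0.013 at this size; 4 SD band
  expect_equal(auc0, 0.5, tolerance = 0.11)

  # 3 SD shift: per-feature Bayes error Phi(-1.5) ~ 0.067; a linear
  # classifier on 20 features is near perfect on a held-out half
  s3 <- synthetic_spec(200, 200, n_features = 20, effect_size = 3, seed = 9)
  dm3 <- gen_descriptors(s3)
  lab <- unname(attr(dm3, "labels"))
  half <- rep(c(TRUE, FALSE), length.out = 400)
  m <- fit_classifier(dm3$features[half, ], lab[half], "SVM",
                      list(kernel = "linear"), seed = 1)
  pred <- predict(m, dm3$features[!half, ])
  met <- classification_metrics(confusion_counts_from_labels(lab[!half], pred))
  expect_gt(met$ba, 0.95)
})

test_that("docking score generator matches its closed-form AUC", {
  # two unit-variance Gaussians dock_gap apart: AUC = Phi(gap / sqrt(2))
  s <- synthetic_spec(2000, 2000, dock_gap = 2, noise_sd = 1, seed = 21)
  lab <- c(rep(1L, 2000), rep(0L, 2000))
  d <- gen_docking_scores(lab, s)
  expect_equal(roc_auc(-d$dock_score, lab), pnorm(2 / sqrt(2)),
               tolerance = 0.02)

  s0 <- synthetic_spec(1000, 1000, dock_gap = 0, seed = 22)
  lab0 <- c(rep(1L, 1000), rep(0L, 1000))
  d0 <- gen_docking_scores(lab0, s0)
  expect_equal(roc_auc(-d0$dock_score, lab0), 0.5, tolerance = 0.04)
  # actives shift more negative on the raw scale
  expect_lt(mean(d$dock_score[lab == 1]), mean(d$dock_score[lab == 0]))

  expect_error(gen_docking_scores(integer(0), s), "non-empty")
  all0 <- gen_docking_scores(rep(0L, 50), s)
  expect_warning(a <- roc_auc(-all0$dock_score, rep(0L, 50)), "one class")
  expect_true(is.na(a))
})

test_that("downstream AUC is monotone in effect_size in expectation", {
  mean_auc <- function(es) {
    mean(vapply(1:20, function(seed) {
      s <- synthetic_spec(30, 150, n_features = 10, effect_size = es,
                          seed = seed)
      dm <- gen_descriptors(s)
      roc_auc(rowMeans(dm$features), attr(dm, "labels"))
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 0.5, 1.5), mean_auc, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("synthetic CSV round-trips", {
  s <- synthetic_spec(5, 20, n_features = 3, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(s, dir)
  desc <- read.csv(paths$descriptors)
  expect_equal(nrow(desc), 25)
  expect_named(desc, c("id", "label", "feature_1", "feature_2", "feature_3"))
  dock <- read.csv(paths$docking)
  expect_equal(dock$dock_score,
               gen_docking_scores(setNames(desc$label, desc$id), s)$dock_score,
               tolerance = 1e-12)
})
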