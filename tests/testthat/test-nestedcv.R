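test_that("grids match the fixed tuning space and order simplest-first", {
  g <- hyper_grid("RF")
  expect_equal(g$n_estimators, c(50L, 100L, 200L))
  expect_equal(g$max_depth, c(NA, 10L, 20L))
  expect_equal(hyper_grid("SVM"), list(C = c(0.1, 1, 10),
                                       kernel = c("linear", "rbf")))
  expect_equal(hyper_grid("XGB"), list(n_estimators = c(50L, 100L, 200L),
                                       max_depth = c(3L, 5L, 7L)))
  combos <- votedock:::expand_param_grid(g)
  first <- votedock:::combo_as_params(combos, 1)
  # simplest combination first: fewest trees, shallowest finite depth
  expect_equal(first$n_estimators, 50L)
  expect_equal(first$max_depth, 10L)
  svm_first <- votedock:::combo_as_params(
    votedock:::expand_param_grid(hyper_grid("SVM")), 1)
  expect_equal(svm_first, list(C = 0.1, kernel = "linear"))
})

test_that("tuning returns the single combination of a degenerate grid", {
  d <- toy_separable(15, gap = 3, seed = 1)
  p <- tune_hyperparameters(d$x, d$y, "RF",
                            grid = list(n_estimators = 100L, max_depth = 10L),
                            seed = 2)
  expect_equal(p, list(n_estimators = 100L, max_depth = 10L))
})

test_that("perfect separability triggers the simplicity tie-break", {
  d <- toy_separable(25, gap = 8, seed = 3)
  p <- tune_hyperparameters(d$x, d$y, "RF",
                            grid = list(n_estimators = c(50L, 100L),
                                        max_depth = c(NA, 10L)),
                            seed = 4)
  expect_equal(p$n_estimators, 50L)
  expect_equal(p$max_depth, 10L)
})

test_that("planted XOR signal selects deeper trees", {
  set.seed(12)
  x <- matrix(rnorm(240 * 4), 240)
  y <- as.integer(xor(x[, 1] > 0, x[, 2] > 0))
  picks <- vapply(1:3, function(s) {
    tune_hyperparameters(x, y, "XGB",
                         grid = list(n_estimators = 50L,
                                     max_depth = c(1L, 5L)),
                         seed = s)$max_depth
  }, integer(1))
  expect_gte(sum(picks == 5L), 2)
})

test_that("modal parameter selection takes strict modes and simple ties", {
  same <- replicate(9, list(n_estimators = 100L, max_depth = 10L),
                    simplify = FALSE)
  expect_equal(modal_params(same), list(n_estimators = 100L, max_depth = 10L))

  mixed <- c(replicate(5, list(n_estimators = 100L), simplify = FALSE),
             replicate(4, list(n_estimators = 200L), simplify = FALSE))
  expect_equal(modal_params(mixed)$n_estimators, 100L)

  # 4/4 tie between depth 10 and none (plus one 20): shallower finite wins
  tie <- c(replicate(4, list(max_depth = 10L), simplify = FALSE),
           replicate(4, list(max_depth = NA), simplify = FALSE),
           list(list(max_depth = 20L)))
  expect_equal(modal_params(tie)$max_depth, 10L)

  expect_error(modal_params(list()), "non-empty")
})

test_that("nested CV recovers signal and stays at chance without one", {
  # no signal: mean MCC ~ 0
  s0 <- synthetic_spec(20, 100, n_features = 6, effect_size = 0, seed = 14)
  dm0 <- gen_descriptors(s0)
  y0 <- unname(attr(dm0, "labels"))
  plan0 <- make_fold_plan(y0, outer_k = 5, n_subsets = 5, seed = 14)
  rep0 <- run_nested_cv(dm0$features, y0, "RF", plan0, tune = FALSE)
  expect_lt(abs(rep0$mean_mcc), 0.2)

  # strong signal: mean BA > 0.9; validation folds stay imbalanced
  s3 <- synthetic_spec(30, 150, n_features = 10, effect_size = 3, seed = 15)
  dm3 <- gen_descriptors(s3)
  y3 <- unname(attr(dm3, "labels"))
  plan3 <- make_fold_plan(y3, outer_k = 5, n_subsets = 5, seed = 15)
  rep3 <- run_nested_cv(dm3$features, y3, "RF", plan3, tune = FALSE)
  expect_gt(rep3$mean_ba, 0.9)
  glob <- mean(y3)
  for (f in 1:5) {
    val <- which(plan3$outer == f)
    expect_lte(abs(sum(y3[val]) - glob * length(val)), 1)
  }
  # report aggregates are recomputable from the per-fold values
  expect_equal(rep3$mean_mcc, mean(rep3$folds$mcc))
  expect_equal(rep3$sd_ba, sd(rep3$folds$ba))
  expect_error(run_nested_cv(dm3$features, y0, "RF", plan3), "match")
})

test_that("final ensemble retraining honors the undersampling contract", {
  s <- synthetic_spec(30, 150, n_features = 8, effect_size = 4, seed = 16)
  dm <- gen_descriptors(s)
  y <- unname(attr(dm, "labels"))
  ens <- retrain_final(dm$features, y, "RF", n_subsets = 9, seed = 16)
  expect_s3_class(ens, "ensemble_model")
  expect_length(ens$members, 9L)
  # strongly separable data: members nearly always agree on held-out points
  s2 <- synthetic_spec(40, 200, n_features = 8, effect_size = 4, seed = 17)
  dm2 <- gen_descriptors(s2)
  votes <- predict_votes(ens, dm2$features)
  member_cols <- as.matrix(votes[, grep("^member_", names(votes))])
  agree <- rowMeans(member_cols) %in% c(0, 1)
  expect_gt(mean(agree), 0.95)
})

test_that("paired Wilcoxon comparison behaves at the edges", {
  a <- c(0.2, 0.3, 0.25, 0.4, 0.35, 0.3, 0.28, 0.33, 0.31)
  expect_warning(p <- compare_paired_metrics(a, a), "zero")
  expect_equal(p, 1)
  # all-positive distinct differences, n = 9: exact signed-rank p = 2 / 2^9
  expect_equal(compare_paired_metrics(a, a + seq(0.01, 0.09, by = 0.01)),
               2 / 2^9, tolerance = 1e-10)
  # uniform +1 shift (tied ranks -> normal approximation) is still significant
  expect_lt(compare_paired_metrics(a, a + 1), 0.05)
  expect_error(compare_paired_metrics(a, a[-1]), "length")
})
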