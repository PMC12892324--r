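test_that("descriptor_matrix enforces its invariants", {
  m <- matrix(1:6, nrow = 2)
  dm <- descriptor_matrix(c("a", "b"), m, "continuous")
  expect_equal(dm$width, 3L)
  expect_error(descriptor_matrix("a", m, "continuous"), "rows")
  expect_error(descriptor_matrix(c("a", "a"), m, "continuous"), "unique")
  m2 <- m; m2[1] <- NA
  expect_error(descriptor_matrix(c("a", "b"), m2, "continuous"), "missing")
  expect_error(descriptor_matrix(c("a", "b"), m, "binary_fingerprint"),
               "outside")
})

test_that("ecfp4 is deterministic and separates distinct environments", {
  fp1 <- ecfp4(c("c1ccccc1", "C1CCCCC1"), n_bits = 512)
  fp2 <- ecfp4(c("c1ccccc1", "C1CCCCC1"), n_bits = 512)
  expect_identical(fp1$features, fp2$features)
  expect_identical(fp1$kind, "binary_fingerprint")
  expect_equal(fp1$width, 512L)
  # benzene vs cyclohexane differ in at least one bit
  expect_gt(sum(fp1$features[1, ] != fp1$features[2, ]), 0)
  expect_error(ecfp4("not_a_smiles", ids = "badid"), "badid")
})

test_that("tanimoto agrees with a set-intersection oracle", {
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  # bits {1,2,3} vs {2,3,4} -> 2/4
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(rep(0, 8), rep(0, 8)), 1)  # both all-zero
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")

  # real fingerprints vs brute-force bit-set comparison, and symmetry
  fps <- ecfp4(c("CCO", "CCN", "c1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O"),
               n_bits = 256)
  f <- fps$features
  for (i in 1:3) for (j in (i + 1):4) {
    inter <- sum(f[i, ] & f[j, ])
    uni <- sum(f[i, ] | f[j, ])
    expect_equal(tanimoto(f[i, ], f[j, ]), inter / uni)
    expect_equal(tanimoto(f[i, ], f[j, ]), tanimoto(f[j, ], f[i, ]))
  }
})

test_that("crippen logP orders molecules by hydrophobicity", {
  expect_equal(crippen_logp("CCO"), crippen_logp("CCO"))
  # hexane > ethanol
  expect_gt(crippen_logp("CCCCCC"), crippen_logp("CCO"))
  # chlorine substituent on an azole scaffold raises logP
  expect_gt(crippen_logp("Clc1ccc(Cn2cncn2)cc1"),
            crippen_logp("c1ccc(Cn2cncn2)cc1"))
  expect_error(crippen_logp("xx)("), "unparseable")
})

test_that("continuous descriptor tables round-trip and validate", {
  dir <- withr::local_tempdir()
  s <- synthetic_spec(10, 30, n_features = 4, seed = 6)
  dm <- gen_descriptors(s)
  path <- file.path(dir, "cddd.csv")
  write_descriptor_table(dm, path)
  back <- load_descriptor_table(path)
  expect_equal(back$features, dm$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$ids, dm$ids)

  # alignment to a requested id order, with warning for unmatched ids
  some <- rev(dm$ids[1:5])
  expect_warning(sub <- load_descriptor_table(path, ids = some), "absent")
  expect_identical(sub$ids, some)
  expect_equal(sub$features[1, ], dm$features[match(some[1], dm$ids), ],
               ignore_attr = TRUE)

  # missing cells rejected with offending row named
  df <- read.csv(path)
  df$feature_2[3] <- NA
  bad <- file.path(dir, "bad.csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_descriptor_table(bad), df$id[3])

  # generator parameters recovered from a written table
  s2 <- synthetic_spec(500, 500, n_features = 3, effect_size = 1, seed = 31)
  dm2 <- gen_descriptors(s2)
  p2 <- file.path(dir, "gauss.csv")
  write_descriptor_table(dm2, p2)
  back2 <- load_descriptor_table(p2)
  act <- back2$features[attr(dm2, "labels") == 1, ]
  expect_equal(unname(colMeans(act)), rep(1, 3), tolerance = 0.15)
  expect_equal(unname(apply(act, 2, sd)), rep(1, 3), tolerance = 0.15)
})
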