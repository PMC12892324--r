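test_that("single-compound standardization applies the fixed rule order", {
  # sodium salt: strip counterion, neutralize carboxylate
  r <- standardize_compound("O=C([O-])c1ccccc1.[Na+]")
  expect_equal(r$smiles_std, "O=C(O)c1ccccc1")
  expect_equal(r$reject_reason, "none")
  expect_match(r$log, "salt_strip")
  expect_match(r$log, "neutralize")

  # enantiomers collapse to one canonical form
  expect_equal(standardize_compound("C[C@@H](C(=O)O)N")$smiles_std,
               standardize_compound("C[C@H](C(=O)O)N")$smiles_std)

  # carbon-free species are inorganic; off-allowlist atoms are metal
  expect_equal(standardize_compound("[O-][Cl+3]([O-])([O-])[O-]")$reject_reason,
               "inorganic")
  expect_equal(standardize_compound("CCCC[Sn](CCCC)(CCCC)CCCC")$reject_reason,
               "metal")

  # quaternary N is a permanent cation and stays charged
  expect_equal(standardize_compound("C[N+](C)(C)C.[Cl-]")$smiles_std,
               "C[N+](C)(C)C")

  # unparseable input is a reject, not an exception
  expect_equal(standardize_compound("xx)(")$reject_reason, "parse_error")
  expect_error(standardize_compound(""), "non-empty")
})

test_that("standardization is idempotent", {
  toy <- gen_toy_smiles()
  once <- vapply(toy$smiles, function(s) {
    r <- standardize_compound(s)
    if (is.na(r$smiles_std)) NA_character_ else r$smiles_std
  }, character(1), USE.NAMES = FALSE)
  for (s in once[!is.na(once)]) {
    expect_equal(standardize_compound(s)$smiles_std, s)
  }
})

test_that("toy fixture standardizes exactly as frozen", {
  toy <- gen_toy_smiles()
  std <- standardize_dataset(toy[c("id", "smiles")])
  rejected <- std$rejected
  expect_setequal(rejected$id, toy$id[toy$expect_reject != "none"])
  expect_equal(rejected$reject_reason,
               toy$expect_reject[match(rejected$id, toy$id)])
  kept_expect <- toy[toy$expect_reject == "none", ]
  for (i in seq_len(nrow(std$records))) {
    expect_equal(std$records$smiles_std[i],
                 kept_expect$expect_std[match(std$records$id[i],
                                              kept_expect$id)])
  }
  # the two enantiomers merged into one record
  expect_equal(std$report$merged, 1L)
  expect_equal(std$duplicate_map$removed_id, "alanine_S")
  expect_equal(std$duplicate_map$kept_id, "alanine_R")
})

test_that("dataset bookkeeping partitions the input exactly", {
  toy <- gen_toy_smiles()
  toy$label <- c(1, 0, 0, 1, 0, 0, 1, 0)  # enantiomer pair disagrees
  std <- standardize_dataset(toy[c("id", "smiles", "label")])
  rep <- std$report
  expect_equal(rep$kept + rep$rejected + rep$merged, rep$input)
  # conflicting duplicate labels resolve to active, with a note
  ala <- std$records[std$records$id == "alanine_R", ]
  expect_equal(ala$label, 1L)
  expect_match(ala$merge_note, "label_conflict")
  expect_equal(ala$merged_from, "alanine_S")

  expect_error(standardize_dataset(data.frame(id = c("a", "a"),
                                              smiles = c("C", "CC"))),
               "duplicate input ids")

  empty <- standardize_dataset(data.frame(id = character(0),
                                          smiles = character(0)))
  expect_equal(empty$report$input, 0L)
  expect_equal(nrow(empty$duplicate_map), 0L)
})

test_that("compound readers handle CSV and SDF", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cmpds.csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "c1ccccc1"),
                       label = c(1, 0)), csv, row.names = FALSE)
  df <- read_compounds(csv)
  expect_equal(df$smiles, c("CCO", "c1ccccc1"))

  sdf <- file.path(dir, "cmpds.sdf")
  writeLines(c("methane", "", "",
               "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), sdf)
  sdf_df <- read_compounds(sdf)
  expect_equal(nrow(sdf_df), 1L)
  expect_equal(sdf_df$id, "methane")
  expect_equal(sdf_df$smiles, "C")

  expect_error(read_compounds(file.path(dir, "nope.csv")), "not found")
})
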