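#' Specification of a synthetic screening dataset
#'
#' Describes the statistical world the synthetic generator draws from:
#' two class-conditional Gaussian feature distributions separated by
#' `effect_size` standard deviations, and raw docking scores whose negated
#' values are on average `dock_gap` higher for actives. Defaults mirror the
#' screening regime the package targets: 84 actives vs 1048 inactives
#' (about 1:12.5 imbalance).
#'
#' @param n_active number of active compounds (>= 1).
#' @param n_inactive number of inactive compounds (>= 1).
#' @param n_features number of continuous descriptor columns.
#' @param effect_size per-feature mean shift of actives, in SD units (>= 0).
#' @param dock_gap mean difference of negated docking scores, actives minus
#'   inactives. Actives dock `dock_gap` units more negative on the raw scale.
#' @param noise_sd standard deviation of the docking-score noise (> 0).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 84L, n_inactive = 1048L,
                           n_features = 20L, effect_size = 1,
                           dock_gap = 1, noise_sd = 1, seed = 1L) {
  spec <- list(
    n_active = assert_count(n_active, "n_active"),
    n_inactive = assert_count(n_inactive, "n_inactive"),
    n_features = assert_count(n_features, "n_features"),
    effect_size = assert_number(effect_size, "effect_size", min = 0),
    dock_gap = assert_number(dock_gap, "dock_gap"),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  structure(spec, class = "synthetic_spec")
}

# Raw docking baseline: realistic Glide-like scale, so that thresholds near
# -6.5 are meaningful on synthetic data (actives shift more negative).
DOCK_BASELINE <- -5.0

#' Generate a labeled synthetic descriptor matrix
#'
#' Actives are drawn N(effect_size, 1) per feature, inactives N(0, 1).
#' Actives occupy the first `n_active` rows.
#'
#' @param spec a [synthetic_spec()].
#' @param binarize if `TRUE`, features are thresholded at 0 into 0/1 and the
#'   matrix is tagged `binary_fingerprint` (crude stand-in for fingerprints).
#' @return a [descriptor_matrix()] with a `labels` attribute (integer 0/1,
#'   named by compound id).
#' @export
gen_descriptors <- function(spec, binarize = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_active + spec$n_inactive
  labels <- c(rep(1L, spec$n_active), rep(0L, spec$n_inactive))
  ids <- sprintf("cmpd_%05d", seq_len(n))
  feats <- with_seed(spec$seed, {
    m <- matrix(stats::rnorm(n * spec$n_features), nrow = n)
    m[labels == 1L, ] <- m[labels == 1L, ] + spec$effect_size
    m
  })
  kind <- "continuous"
  if (binarize) {
    feats <- (feats > 0) + 0
    kind <- "binary_fingerprint"
  }
  colnames(feats) <- sprintf("feature_%d", seq_len(spec$n_features))
  dm <- descriptor_matrix(ids, feats, kind)
  attr(dm, "labels") <- setNames(labels, ids)
  dm
}

#' Generate synthetic raw docking scores
#'
#' Inactives score at the baseline (-5.0); actives score on average
#' `dock_gap` units more negative, i.e. their negated scores are higher.
#' More negative = stronger predicted binding, matching docking-engine
#' conventions.
#'
#' @param labels binary label vector (0/1 or active/inactive); names, if
#'   present, become compound ids.
#' @param spec a [synthetic_spec()] supplying `dock_gap`, `noise_sd`, `seed`.
#' @return data.frame with columns `id`, `dock_score`, `docked` (all TRUE).
#' @export
gen_docking_scores <- function(labels, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(labels) < 1L) vd_stop("label vector must be non-empty")
  ids <- names(labels) %||% sprintf("cmpd_%05d", seq_along(labels))
  labels <- as_binary_labels(labels)
  scores <- with_seed(spec$seed + 1L, {
    mu <- ifelse(labels == 1L, DOCK_BASELINE - spec$dock_gap, DOCK_BASELINE)
    stats::rnorm(length(labels), mean = mu, sd = spec$noise_sd)
  })
  data.frame(id = ids, dock_score = scores, docked = TRUE,
             stringsAsFactors = FALSE)
}

#' Hand-curated SMILES fixture with known standardization outcomes
#'
#' Covers the rule set of [standardize_compound()]: salt stripping, charge
#' neutralization, stereochemistry removal with duplicate collapse, and
#' rejection of inorganic (carbon-free) and metal-containing species.
#' Expected canonical forms are frozen from the reference toolkit.
#'
#' @return data.frame with columns `id`, `smiles`, `expect_std` (NA when
#'   rejected) and `expect_reject` ("none", "inorganic" or "metal").
#' @export
gen_toy_smiles <- function() {
  data.frame(
    id = c("sodium_benzoate", "ethylammonium_chloride", "alanine_R",
           "alanine_S", "perchlorate", "tributyltin_sub",
           "tetramethylammonium_cl", "benzene"),
    smiles = c("O=C([O-])c1ccccc1.[Na+]",
               "CC[NH3+].[Cl-]",
               "C[C@@H](C(=O)O)N",
               "C[C@H](C(=O)O)N",
               "[O-][Cl+3]([O-])([O-])[O-]",
               "CCCC[Sn](CCCC)(CCCC)CCCC",
               "C[N+](C)(C)C.[Cl-]",
               "c1ccccc1"),
    expect_std = c("O=C(O)c1ccccc1",
                   "CCN",
                   "CC(N)C(=O)O",
                   "CC(N)C(=O)O",
                   NA,
                   NA,
                   "C[N+](C)(C)C",
                   "c1ccccc1"),
    expect_reject = c("none", "none", "none", "none", "inorganic", "metal",
                      "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic dataset to CSV files
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`descriptors`, `docking`).
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dm <- gen_descriptors(spec)
  labels <- attr(dm, "labels")
  desc <- data.frame(id = dm$ids, label = unname(labels),
                     as.data.frame(dm$features), check.names = FALSE)
  dock <- gen_docking_scores(labels, spec)
  paths <- list(descriptors = file.path(dir, "descriptors.csv"),
                docking = file.path(dir, "docking.csv"))
  write_table_csv(desc, paths$descriptors)
  write_table_csv(dock, paths$docking)
  invisible(paths)
}
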