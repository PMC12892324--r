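Package: votedock
Title: Consensus of Undersampling Vote Ensembles and Docking Scores for
    Transporter-Inhibition Screening
Version: 0.1.0
Authors@R:
    person("Mara", "Lindqvist", email = "mara.lindqvist@example.org",
           role = c("aut", "cre"))
Description: Classifies small molecules as inhibitors or non-inhibitors of a
    membrane transporter (the sodium-iodide symporter use case) by fusing two
    evidence channels: majority-vote scores from ensembles of classifiers
    trained on undersampled subsets of a strongly imbalanced screening
    dataset, and externally supplied docking scores. Provides a molecule
    standardization workflow (salt stripping, charge neutralization,
    stereochemistry removal, inorganic/metal filters) backed by RDKit,
    ECFP4/Tanimoto similarity and applicability-domain analysis, nested
    cross-validation with within-fold undersampling and majority voting,
    fixed-bound min-max score normalization, kernel-density-estimate decision
    thresholds, full confusion-matrix metrics (MCC, balanced accuracy, and
    friends), missing-channel imputation policies, and a seeded synthetic
    data generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the
    PATH (used for SMILES standardization, fingerprints and logP only)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
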