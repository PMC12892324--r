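#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow with the shipped
#' defaults: 9 outer folds, 5 inner folds, 9 undersampled subsets, vote
#' bounds (0, 9), negated-docking bounds (-2.80, 12.073), consensus
#' threshold 0.82 (active strictly above), docking threshold -6.52 (active
#' at or below, raw scale), pChEMBL threshold 6, 80/20 stratified split.
#'
#' @param ... overrides for any default (unknown keys are rejected). Paths:
#'   `compounds_csv` (id,smiles,label[,cytotoxic]), `descriptors_csv`
#'   (id,label,feature_*), `dock_csv` (id,dock_score[,docked]), `out_dir`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    descriptor_kind = "continuous",
    n_bits = 2048L,
    algorithm = "RF",
    outer_k = 9L,
    inner_k = 5L,
    n_subsets = 9L,
    train_frac = 0.8,
    tune = FALSE,
    run_cv = TRUE,
    vote_min = 0, vote_max = 9,
    dock_min = -2.80, dock_max = 12.073,
    consensus_threshold = 0.82,
    docking_threshold = -6.52,
    pchembl_threshold = 6,
    compounds_csv = NULL,
    descriptors_csv = NULL,
    dock_csv = NULL,
    out_dir = "votedock_run"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) vd_stop("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
  structure(modifyList(defaults, overrides), class = "pipeline_config")
}

#' Read a pipeline configuration from a key = value text file
#'
#' Blank lines and `#` comments are ignored; values are coerced to numeric
#' or logical where possible.
#'
#' @param path config file.
#' @param ... further overrides applied on top of the file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) vd_stop("malformed config line(s): %s",
                        paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(pipeline_config, modifyList(vals, list(...)))
}

pipeline_log <- function(state, stage, fmt, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...))
  cat(line, "\n", file = state$log_path, append = TRUE, sep = "")
  message(line)
}

#' Run the end-to-end pipeline
#'
#' Standardize (if raw SMILES are supplied) -> featurize -> stratified 80/20
#' split -> nested CV with undersampling -> final ensemble retraining ->
#' test-set vote prediction -> channel imputation and consensus scoring ->
#' metrics -> applicability domain (when fingerprints are available). Every
#' stage writes its artifact under `config$out_dir` plus a log line; a
#' manifest records the configuration, package version and seed. A stage
#' failure halts the run with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the main artifacts (paths and in-memory
#'   results: `cv`, `ensemble`, `votes`, `consensus`, `metrics`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(config$out_dir, "run.log"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      vd_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("votedock")),
                   r_version = R.version.string, seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)

  duplicate_map <- data.frame(removed_id = character(0),
                              kept_id = character(0))
  smiles_std <- NULL

  if (!is.null(config$compounds_csv)) {
    dat <- stage("standardize", {
      raw <- read_compounds(config$compounds_csv)
      std <- standardize_dataset(raw)
      write_standardized(std, config$out_dir)
      pipeline_log(state, "standardize",
                   "kept %d, rejected %d, merged %d of %d",
                   std$report$kept, std$report$rejected, std$report$merged,
                   std$report$input)
      std
    })
    duplicate_map <- dat$duplicate_map
    smiles_std <- setNames(dat$records$smiles_std, dat$records$id)
    dm <- stage("featurize", {
      if (identical(config$descriptor_kind, "binary_fingerprint")) {
        ecfp4(dat$records$smiles_std, n_bits = config$n_bits,
              ids = dat$records$id)
      } else if (!is.null(config$descriptors_csv)) {
        load_descriptor_table(config$descriptors_csv, ids = dat$records$id)
      } else {
        vd_stop(paste("continuous descriptors requested but no",
                      "descriptors_csv given"))
      }
    })
    labels <- setNames(as_binary_labels(dat$records$label), dat$records$id)
  } else if (!is.null(config$descriptors_csv)) {
    dm <- stage("featurize", {
      df <- read_table_csv(config$descriptors_csv)
      if (!all(c("id", "label") %in% names(df))) {
        vd_stop("descriptor CSV needs 'id' and 'label' columns")
      }
      descriptor_matrix(as.character(df$id),
                        as.matrix(df[setdiff(names(df), c("id", "label"))]),
                        config$descriptor_kind)
    })
    df <- read_table_csv(config$descriptors_csv)
    labels <- setNames(as_binary_labels(df$label), as.character(df$id))
  } else {
    vd_stop("config needs either compounds_csv or descriptors_csv")
  }
  pipeline_log(state, "featurize", "%d compounds x %d features (%s)",
               length(dm$ids), dm$width, dm$kind)

  split <- stage("split", {
    in_train <- stratified_split(labels[dm$ids], config$train_frac,
                                 config$seed)
    write_table_csv(data.frame(id = dm$ids, label = unname(labels[dm$ids]),
                               set = ifelse(in_train, "train", "test")),
                    file.path(config$out_dir, "split.csv"))
    in_train
  })
  pipeline_log(state, "split", "%d train / %d test (stratified %.0f/%.0f)",
               sum(split), sum(!split), 100 * config$train_frac,
               100 * (1 - config$train_frac))

  X <- dm$features
  y <- unname(labels[dm$ids])
  Xtr <- X[split, , drop = FALSE]
  ytr <- y[split]

  selected <- default_params(config$algorithm)
  cv <- NULL
  if (isTRUE(config$run_cv)) {
    cv <- stage("nested_cv", {
      plan <- make_fold_plan(ytr, config$outer_k, config$n_subsets,
                             config$seed)
      rep <- run_nested_cv(Xtr, ytr, config$algorithm, plan,
                           tune = isTRUE(config$tune))
      write_table_csv(rep$folds, file.path(config$out_dir, "cv_report.csv"))
      rep
    })
    selected <- cv$selected_params
    pipeline_log(state, "nested_cv", "MCC %.3f +/- %.3f, BA %.3f +/- %.3f",
                 cv$mean_mcc, cv$sd_mcc, cv$mean_ba, cv$sd_ba)
  }

  ensemble <- stage("retrain", {
    retrain_final(Xtr, ytr, config$algorithm, selected,
                  n_subsets = config$n_subsets, seed = config$seed,
                  kind = dm$kind)
  })
  pipeline_log(state, "retrain", "%d-member %s ensemble (%s)",
               ensemble$n_subsets, ensemble$algorithm, ensemble$signature)
  save_ensemble(ensemble, file.path(config$out_dir, "model_bundle"))

  votes <- stage("predict", {
    test_dm <- descriptor_matrix(dm$ids[!split], X[!split, , drop = FALSE],
                                 dm$kind)
    v <- predict_votes(ensemble, test_dm)
    write_table_csv(v, file.path(config$out_dir, "votes.csv"))
    v
  })

  consensus <- metrics <- NULL
  if (!is.null(config$dock_csv)) {
    consensus <- stage("consensus", {
      dock <- read_table_csv(config$dock_csv)
      if (!all(c("id", "dock_score") %in% names(dock))) {
        vd_stop("docking CSV needs 'id' and 'dock_score' columns: %s",
                config$dock_csv)
      }
      ch <- impute_missing(votes$id, duplicate_map, dock, votes)
      res <- classify_consensus(ch, config$consensus_threshold,
                                norm_bounds(config$dock_min, config$dock_max),
                                norm_bounds(config$vote_min, config$vote_max))
      write_table_csv(res, file.path(config$out_dir, "consensus.csv"))
      res
    })
    metrics <- stage("metrics", {
      ytest <- y[!split]
      avail <- consensus$predicted_label != "not_available"
      cc <- confusion_counts_from_labels(
        ytest[avail], as.integer(consensus$predicted_label[avail] == "active"))
      m <- classification_metrics(cc)
      m$roc_auc_consensus <- roc_auc(consensus$consensus, ytest)
      m$roc_auc_votes <- roc_auc(votes$votes, ytest)
      m$roc_auc_dock <- roc_auc(consensus$norm_dock, ytest)
      jsonlite::write_json(m[setdiff(names(m), "flags")],
                           file.path(config$out_dir, "metrics.json"),
                           auto_unbox = TRUE, null = "null", digits = NA)
      m
    })
    pipeline_log(state, "metrics", "consensus MCC %.3f, BA %.3f, AUC %.3f",
                 metrics$mcc, metrics$ba, metrics$roc_auc_consensus)
  }

  if (dm$kind == "binary_fingerprint") {
    stage("applicability", {
      ref <- descriptor_matrix(dm$ids[split], X[split, , drop = FALSE],
                               dm$kind)
      qry <- descriptor_matrix(dm$ids[!split], X[!split, , drop = FALSE],
                               dm$kind)
      rep <- knn_tanimoto(qry, ref, k = 5L, ref_labels = y[split])
      write_table_csv(rep, file.path(config$out_dir, "neighbors.csv"))
      jsonlite::write_json(list(mean_nn_similarity = mean_nn_similarity(rep)),
                           file.path(config$out_dir, "applicability.json"),
                           auto_unbox = TRUE, digits = NA)
      pipeline_log(state, "applicability", "mean NN similarity %.3f",
                   mean_nn_similarity(rep))
    })
  } else {
    pipeline_log(state, "applicability",
                 "skipped (continuous descriptors; no fingerprints)")
  }

  invisible(list(out_dir = config$out_dir, cv = cv, ensemble = ensemble,
                 votes = votes, consensus = consensus, metrics = metrics))
}
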