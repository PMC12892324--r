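#' Apply an ensemble to new compounds: votes and majority labels
#'
#' Each ensemble member casts a binary vote; the vote sum (0-9 for the
#' standard nine-member ensemble) is the ML channel's score and the majority
#' vote (>= 5 of 9) the predicted label.
#'
#' @param model an [retrain_final()] `ensemble_model`.
#' @param X a [descriptor_matrix()] (kind and width are checked against the
#'   model) or a plain numeric matrix (width checked only).
#' @return data.frame with `id`, `votes`, `majority_label`
#'   ("active"/"inactive"), and one `member_<i>` column per ensemble member.
#' @export
predict_votes <- function(model, X) {
  stopifnot(inherits(model, "ensemble_model"))
  if (inherits(X, "descriptor_matrix")) {
    if (!identical(X$kind, model$kind)) {
      vd_stop("descriptor kind '%s' does not match the model's '%s'",
              X$kind, model$kind)
    }
    ids <- X$ids
    feats <- X$features
  } else {
    feats <- as.matrix(X)
    ids <- rownames(feats) %||% sprintf("row_%d", seq_len(nrow(feats)))
  }
  if (ncol(feats) != model$width) {
    vd_stop("descriptor width %d does not match the model's %d", ncol(feats),
            model$width)
  }
  member_votes <- vapply(model$members, function(m) predict(m, feats),
                         integer(nrow(feats)))
  if (is.null(dim(member_votes))) {
    member_votes <- matrix(member_votes, nrow = nrow(feats))
  }
  votes <- as.integer(rowSums(member_votes))
  out <- data.frame(id = ids, votes = votes,
                    majority_label = ifelse(votes * 2L > model$n_subsets,
                                            "active", "inactive"),
                    stringsAsFactors = FALSE)
  colnames(member_votes) <- sprintf("member_%d", seq_along(model$members))
  cbind(out, member_votes)
}

#' ROC AUC of vote sums
#'
#' Area under the ROC curve of the vote-sum score against true labels, with
#' midrank tie handling (pairwise concordance with ties counted one half).
#'
#' @param vote_results output of [predict_votes()] (or any data.frame with a
#'   `votes` column), in the same order as `labels`.
#' @param labels binary ground-truth labels.
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class present.
#' @export
vote_roc <- function(vote_results, labels) {
  votes <- if (is.data.frame(vote_results)) vote_results$votes else vote_results
  roc_auc(votes, labels)
}

#' Persist / restore an ensemble model bundle
#'
#' The bundle is a directory holding one serialized member per file plus a
#' JSON metadata record (algorithm, parameters, seed, descriptor kind,
#' training signature).
#'
#' @param model an `ensemble_model`.
#' @param dir bundle directory (created; must not already contain a bundle).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "ensemble_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = 1L, algorithm = model$algorithm,
               params = model$params, n_subsets = model$n_subsets,
               kind = model$kind, width = model$width, seed = model$seed,
               signature = model$signature)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  for (i in seq_along(model$members)) {
    saveRDS(model$members[[i]], file.path(dir, sprintf("member_%02d.rds", i)))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) vd_stop("no model bundle at %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) != meta$n_subsets) {
    vd_stop("bundle at %s has %d members, metadata says %d", dir,
            length(files), meta$n_subsets)
  }
  params <- as.list(meta$params)
  if (!is.null(params$max_depth) && is.null(params$max_depth[[1]])) {
    params$max_depth <- NA
  }
  structure(list(members = lapply(files, readRDS), algorithm = meta$algorithm,
                 params = params, n_subsets = meta$n_subsets,
                 kind = meta$kind, width = meta$width, seed = meta$seed,
                 signature = meta$signature),
            class = "ensemble_model")
}
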