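#' Hyperparameter grids
#'
#' The fixed tuning grids for each algorithm:
#' RF `n_estimators` \{50, 100, 200\} x `max_depth` \{none, 10, 20\};
#' SVM `C` \{0.1, 1, 10\} x `kernel` \{linear, rbf\};
#' XGB `n_estimators` \{50, 100, 200\} x `max_depth` \{3, 5, 7\}.
#'
#' @param algorithm "RF", "SVM" or "XGB".
#' @return named list of parameter value vectors (`NA` = no depth limit).
#' @export
hyper_grid <- function(algorithm = c("RF", "SVM", "XGB")) {
  switch(match.arg(algorithm),
         RF = list(n_estimators = c(50L, 100L, 200L),
                   max_depth = c(NA, 10L, 20L)),
         SVM = list(C = c(0.1, 1, 10), kernel = c("linear", "rbf")),
         XGB = list(n_estimators = c(50L, 100L, 200L),
                    max_depth = c(3L, 5L, 7L)))
}

# Complexity rank of one parameter value; lower = simpler. Used for all
# tie-breaking (tuning and modal selection): fewer estimators, shallower
# finite depth (depth "none" is the deepest), smaller C, linear before rbf.
param_value_rank <- function(name, value) {
  if (name == "kernel") return(match(value, c("linear", "rbf")))
  if (name == "max_depth" && (is.null(value) || is.na(value))) return(Inf)
  as.numeric(value)
}

# Expand a grid into a data.frame of combos ordered simplest-first.
expand_param_grid <- function(grid) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ranks <- sapply(names(grid), function(nm) {
    vapply(combos[[nm]], function(v) param_value_rank(nm, v), numeric(1))
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  combos[do.call(order, as.data.frame(ranks)), , drop = FALSE]
}

combo_as_params <- function(combos, i) {
  p <- as.list(combos[i, , drop = FALSE])
  lapply(p, function(v) if (is.factor(v)) as.character(v) else v)
}

#' Tune hyperparameters by inner cross-validation
#'
#' Evaluates every grid combination with stratified `inner_k`-fold CV on the
#' (typically balanced, undersampled) training subset, selecting the
#' combination with the best mean MCC. Ties go to the simplest combination
#' (fewer estimators, shallower finite depth, smaller C, linear before rbf).
#'
#' @param X numeric matrix of the training subset.
#' @param y its binary labels.
#' @param algorithm "RF", "SVM" or "XGB".
#' @param grid parameter grid as from [hyper_grid()].
#' @param inner_k number of inner folds (default 5).
#' @param seed integer seed for fold assignment and model fits.
#' @return named list: the selected parameter set.
#' @export
tune_hyperparameters <- function(X, y, algorithm, grid = hyper_grid(algorithm),
                                 inner_k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  inner_k <- assert_count(inner_k, "inner_k", min = 2L)
  combos <- expand_param_grid(grid)

  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      fold[idx] <- rep_len(seq_len(inner_k), length(idx))[sample.int(length(idx))]
    }
  })

  scores <- rep(-Inf, nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    params <- combo_as_params(combos, ci)
    fold_mcc <- rep(NA_real_, inner_k)
    for (f in seq_len(inner_k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        vd_warn("inner fold %d is degenerate (single class); skipped", f)
        next
      }
      m <- fit_classifier(X[tr, , drop = FALSE], y[tr], algorithm, params,
                          seed = seed + f)
      pred <- predict(m, X[!tr, , drop = FALSE])
      cc <- confusion_counts_from_labels(y[!tr], pred)
      fold_mcc[f] <- classification_metrics(cc)$mcc
    }
    if (all(is.na(fold_mcc))) {
      vd_stop("all %d inner folds were degenerate; cannot tune", inner_k)
    }
    scores[ci] <- mean(fold_mcc, na.rm = TRUE)
  }
  # combos are ordered simplest-first, so the first maximum is the tie-break
  combo_as_params(combos, which.max(scores))
}

#' Per-parameter modal hyperparameters
#'
#' Takes the mode of each parameter independently across a list of selected
#' parameter sets; count ties resolve to the simpler value (same ordering as
#' the tuning tie-break, e.g. a tied finite depth beats "none").
#'
#' @param param_sets non-empty list of named parameter lists.
#' @return named list: the modal parameter set.
#' @export
modal_params <- function(param_sets) {
  if (!length(param_sets)) vd_stop("param_sets must be non-empty")
  nms <- names(param_sets[[1]])
  out <- lapply(nms, function(nm) {
    vals <- lapply(param_sets, `[[`, nm)
    keys <- vapply(vals, function(v) {
      if (is.null(v) || is.na(v)) "NA" else as.character(v)
    }, character(1))
    counts <- table(keys)
    winners <- names(counts)[counts == max(counts)]
    uniq_vals <- vals[!duplicated(keys)]
    uniq_keys <- keys[!duplicated(keys)]
    cand <- uniq_vals[uniq_keys %in% winners]
    ranks <- vapply(cand, function(v) param_value_rank(nm, v), numeric(1))
    cand[[which.min(ranks)]]
  })
  setNames(out, nms)
}

#' Nested cross-validation with within-fold undersampling
#'
#' For each outer fold of `plan`: each of the fold's balanced subsets is
#' tuned in the inner loop (unless `tune = FALSE`), the i-th subset's tuned
#' parameters train the i-th model on that subset, and the resulting models
#' score the untouched, imbalanced validation fold. Each validation compound
#' thus receives `n_subsets` binary predictions; the majority vote (votes
#' strictly greater than half the voters, i.e. >= 5 of 9) gives the fold
#' prediction from which per-fold MCC and balanced accuracy are computed.
#'
#' @param X numeric matrix for all compounds in the plan.
#' @param y binary labels consistent with `plan`.
#' @param algorithm "RF", "SVM" or "XGB".
#' @param plan a [make_fold_plan()] built from `y`.
#' @param grid tuning grid; defaults to [hyper_grid()] for the algorithm.
#' @param tune if `FALSE`, skip inner-loop tuning and use `params`
#'   (default-parameter CV, the tuned-vs-default comparison arm).
#' @param params parameter set used when `tune = FALSE` (default:
#'   [default_params()]).
#' @param seed base seed for model fits (default: the plan's seed).
#' @return object of class `cv_report`: `folds` (data.frame with per-fold
#'   `mcc`, `ba`), `mean_mcc`, `sd_mcc`, `mean_ba`, `sd_ba`, `fold_params`
#'   (modal parameter set per outer fold), `subset_params`, `selected_params`
#'   (modal set across folds).
#' @export
run_nested_cv <- function(X, y, algorithm, plan, grid = hyper_grid(algorithm),
                          tune = TRUE, params = NULL, seed = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (!identical(y, plan$labels)) {
    vd_stop("labels do not match the fold plan")
  }
  if (nrow(X) != length(y)) vd_stop("X rows != labels")
  seed <- seed %||% plan$seed
  ns <- plan$n_subsets

  fold_mcc <- fold_ba <- numeric(plan$outer_k)
  fold_params <- vector("list", plan$outer_k)
  subset_params <- vector("list", plan$outer_k)

  for (f in seq_len(plan$outer_k)) {
    val <- which(plan$outer == f)
    votes <- matrix(0L, nrow = length(val), ncol = ns)
    pars <- vector("list", ns)
    for (i in seq_len(ns)) {
      sub <- plan$subsets[[f]][[i]]
      p_i <- if (tune) {
        tryCatch(
          tune_hyperparameters(X[sub, , drop = FALSE], y[sub], algorithm,
                               grid, seed = seed + f * 1000L + i),
          error = function(e) vd_stop("outer fold %d, subset %d: %s", f, i,
                                      conditionMessage(e)))
      } else {
        params %||% default_params(algorithm)
      }
      pars[[i]] <- p_i
      m <- fit_classifier(X[sub, , drop = FALSE], y[sub], algorithm, p_i,
                          seed = seed + f * 1000L + 500L + i)
      votes[, i] <- predict(m, X[val, , drop = FALSE])
    }
    pred <- as.integer(rowSums(votes) * 2L > ns)
    met <- classification_metrics(confusion_counts_from_labels(y[val], pred))
    fold_mcc[f] <- met$mcc
    fold_ba[f] <- met$ba
    subset_params[[f]] <- pars
    fold_params[[f]] <- modal_params(pars)
  }

  structure(list(
    algorithm = algorithm,
    folds = data.frame(fold = seq_len(plan$outer_k), mcc = fold_mcc,
                       ba = fold_ba),
    mean_mcc = mean(fold_mcc), sd_mcc = sd(fold_mcc),
    mean_ba = mean(fold_ba), sd_ba = sd(fold_ba),
    fold_params = fold_params, subset_params = subset_params,
    selected_params = modal_params(fold_params),
    tuned = tune, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s): MCC %.3f +/- %.3f, BA %.3f +/- %.3f over %d folds\n",
              x$algorithm, if (x$tuned) "tuned" else "default",
              x$mean_mcc, x$sd_mcc, x$mean_ba, x$sd_ba, nrow(x$folds)))
  invisible(x)
}

#' Retrain the final undersampling ensemble
#'
#' Splits the inactives of the full training set into `n_subsets` balanced
#' subsets (each joined with all actives) and fits one model per subset with
#' the supplied (typically modal) parameters.
#'
#' @param X numeric training matrix.
#' @param y binary training labels.
#' @param algorithm "RF", "SVM" or "XGB".
#' @param params shared parameter set for all members.
#' @param n_subsets ensemble size (default 9).
#' @param seed integer seed.
#' @param kind descriptor kind tag carried for prediction-time checks.
#' @return object of class `ensemble_model` with `members` (list of fitted
#'   classifiers), `algorithm`, `params`, `kind`, `width`, `signature`.
#' @export
retrain_final <- function(X, y, algorithm, params = default_params(algorithm),
                          n_subsets = 9L, seed = 1L, kind = "continuous") {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  n_subsets <- assert_count(n_subsets, "n_subsets")
  subs <- undersample_subsets(y, n_subsets, seed)
  members <- lapply(seq_along(subs), function(i) {
    fit_classifier(X[subs[[i]], , drop = FALSE], y[subs[[i]]], algorithm,
                   params, seed = seed + i)
  })
  structure(list(members = members, algorithm = algorithm, params = params,
                 n_subsets = n_subsets, kind = kind, width = ncol(X),
                 seed = seed,
                 signature = sprintf("n=%d;actives=%d;width=%d;kind=%s;seed=%d",
                                     length(y), sum(y), ncol(X), kind, seed)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d x %s, params: %s\n", x$n_subsets,
              x$algorithm,
              paste(names(x$params), unlist(lapply(x$params, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Paired comparison of per-fold metrics
#'
#' Two-sided Wilcoxon signed-rank test on paired per-fold metric vectors
#' (e.g. tuned vs default parameters).
#'
#' @param per_fold_a,per_fold_b equal-length paired metric vectors.
#' @return the two-sided p-value. When every pairwise difference is zero the
#'   test is undefined; 1 is returned with a warning.
#' @export
compare_paired_metrics <- function(per_fold_a, per_fold_b) {
  if (length(per_fold_a) != length(per_fold_b)) {
    vd_stop("paired metric vectors differ in length")
  }
  d <- per_fold_b - per_fold_a
  if (all(d == 0)) {
    vd_warn("all paired differences are zero; p-value reported as 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(per_fold_a, per_fold_b, paired = TRUE,
                alternative = "two.sided")$p.value)
}
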