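#' Normalization bounds
#'
#' Fixed min-max bounds derived once from the training set and then applied
#' unchanged to any new data. The shipped defaults are the vote channel
#' (0, 9) and the negated-docking channel (-2.80, 12.073).
#'
#' @param x_min,x_max bounds with `x_max > x_min`.
#' @return object of class `norm_bounds`.
#' @export
norm_bounds <- function(x_min, x_max) {
  x_min <- assert_number(x_min, "x_min")
  x_max <- assert_number(x_max, "x_max")
  if (x_max <= x_min) vd_stop("x_max (%g) must exceed x_min (%g)", x_max, x_min)
  structure(list(x_min = x_min, x_max = x_max), class = "norm_bounds")
}

#' @rdname norm_bounds
#' @export
vote_bounds <- function() norm_bounds(0, 9)

#' @rdname norm_bounds
#' @export
dock_bounds <- function() norm_bounds(-2.80, 12.073)

#' Fixed-bound min-max normalization
#'
#' `(x - x_min) / (x_max - x_min)`. Values are deliberately *not* clipped:
#' the bounds are frozen from the training set, so scores outside them map
#' outside `[0, 1]`. Clipping would change rankings.
#'
#' @param x numeric vector (NA passes through).
#' @param bounds a [norm_bounds()].
#' @return normalized values.
#' @export
normalize_minmax <- function(x, bounds) {
  stopifnot(inherits(bounds, "norm_bounds"))
  (x - bounds$x_min) / (bounds$x_max - bounds$x_min)
}

#' Consensus score: normalized negated docking plus normalized votes
#'
#' Docking scores are negated before normalization (more negative raw score =
#' stronger predicted binding = higher channel value). The consensus score is
#' the sum of the two normalized channels and lies in `[0, 2]` within the
#' training bounds.
#'
#' @param raw_dock raw docking score(s); NA = missing channel.
#' @param votes vote sum(s) 0..9; NA = missing channel.
#' @param dock_bounds bounds for the *negated* docking score
#'   (default [dock_bounds()]).
#' @param vote_bounds bounds for the vote sum (default [vote_bounds()]).
#' @return numeric consensus score(s); NA where either channel is missing.
#' @export
consensus_score <- function(raw_dock, votes, dock_bounds = votedock::dock_bounds(),
                            vote_bounds = votedock::vote_bounds()) {
  normalize_minmax(-raw_dock, dock_bounds) + normalize_minmax(votes, vote_bounds)
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  vals <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    vd_stop("confusion counts must be non-negative integers")
  }
  structure(as.list(vals), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param truth,pred binary vectors (0/1 or active/inactive) of equal length.
#' @export
confusion_counts_from_labels <- function(truth, pred) {
  truth <- as_binary_labels(truth)
  pred <- as_binary_labels(pred)
  if (length(truth) != length(pred)) vd_stop("truth and pred lengths differ")
  confusion_counts(tp = sum(truth == 1L & pred == 1L),
                   tn = sum(truth == 0L & pred == 0L),
                   fp = sum(truth == 0L & pred == 1L),
                   fn = sum(truth == 1L & pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: accuracy, balanced accuracy (mean of sensitivity
#' and specificity), MCC, precision, recall (= sensitivity), F1, specificity.
#' Degenerate denominators return sentinel values with flags instead of
#' errors: MCC, precision and F1 are 0 when their denominator vanishes;
#' sensitivity/specificity/BA are NA when a class is absent.
#'
#' @param c a [confusion_counts()].
#' @return list of metrics plus a character vector `flags` naming any
#'   degenerate definitions applied.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  n <- tp + tn + fp + fn
  flags <- character(0)

  accuracy <- if (n > 0) (tp + tn) / n else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "no_positives"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    flags <- c(flags, "no_negatives"); NA_real_
  }
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "precision_zero_denominator"); 0
  }
  f1 <- if (!is.na(sens) && precision + sens > 0) {
    2 * precision * sens / (precision + sens)
  } else {
    flags <- c(flags, "f1_zero_denominator"); 0
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (tp * tn - fp * fn) / sqrt(denom)
  } else {
    flags <- c(flags, "mcc_zero_denominator"); 0
  }

  list(accuracy = accuracy, ba = ba, mcc = mcc, precision = precision,
       recall = sens, f1 = f1, sensitivity = sens, specificity = spec,
       flags = flags)
}

#' ROC AUC with midrank tie handling
#'
#' Equivalent to the pairwise concordance probability with ties counted one
#' half (the Mann-Whitney statistic). Higher scores are expected for the
#' positive class.
#'
#' @param scores numeric scores; missing values are excluded (with a count
#'   warning).
#' @param labels binary labels aligned with `scores`.
#' @return AUC in `[0, 1]`, or NA with a warning when only one class remains.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) vd_stop("scores and labels differ in length")
  keep <- !is.na(scores)
  if (any(!keep)) {
    vd_warn("%d compound(s) with missing scores excluded from ROC AUC",
            sum(!keep))
    scores <- scores[keep]
    labels <- labels[keep]
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    vd_warn("ROC AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# evaluate a Gaussian KDE with fixed bandwidth at arbitrary points
kde_eval <- function(sample, at, bw) {
  vapply(at, function(p) mean(dnorm((p - sample) / bw)) / bw, numeric(1))
}

#' Decision threshold from crossing class-conditional KDEs
#'
#' Fits a Gaussian kernel density estimate (Scott's bandwidth) to the scores
#' of each class, locates the crossing point of the two curves in the open
#' interval between the inactive mode and the active mode on a 512-point
#' grid, and refines it by bisection. With several crossings the one
#' maximizing MCC on the input scores is returned; with none, the score
#' cut maximizing MCC is returned with a warning.
#'
#' @param scores_active,scores_inactive numeric score vectors (>= 5 each).
#' @return the threshold, with attributes `method` ("kde_crossing" or
#'   "mcc_fallback") and `orientation` (+1 if actives score higher).
#' @export
kde_threshold <- function(scores_active, scores_inactive) {
  if (length(scores_active) < 5L || length(scores_inactive) < 5L) {
    vd_stop("need at least 5 scores per class (got %d / %d)",
            length(scores_active), length(scores_inactive))
  }
  a <- scores_active[is.finite(scores_active)]
  i <- scores_inactive[is.finite(scores_inactive)]
  orientation <- if (mean(a) >= mean(i)) 1 else -1

  mcc_at <- function(thr) {
    pred <- if (orientation > 0) {
      c(a, i) > thr
    } else {
      c(a, i) < thr
    }
    truth <- c(rep(1L, length(a)), rep(0L, length(i)))
    classification_metrics(confusion_counts_from_labels(truth, as.integer(pred)))$mcc
  }
  fallback <- function() {
    all_s <- sort(unique(c(a, i)))
    cand <- (head(all_s, -1) + tail(all_s, -1)) / 2
    vd_warn("KDE curves do not cross between the class modes; falling back to the MCC-optimal cut")
    thr <- cand[which.max(vapply(cand, mcc_at, numeric(1)))]
    structure(thr, method = "mcc_fallback", orientation = orientation)
  }

  bw_a <- tryCatch(stats::bw.nrd(a), error = function(e) NA_real_)
  bw_i <- tryCatch(stats::bw.nrd(i), error = function(e) NA_real_)
  if (!is.finite(bw_a) || !is.finite(bw_i) || bw_a <= 0 || bw_i <= 0) {
    return(fallback())
  }

  lo_g <- min(a, i) - 3 * max(bw_a, bw_i)
  hi_g <- max(a, i) + 3 * max(bw_a, bw_i)
  grid <- seq(lo_g, hi_g, length.out = 512L)
  da <- kde_eval(a, grid, bw_a)
  di <- kde_eval(i, grid, bw_i)
  mode_a <- grid[which.max(da)]
  mode_i <- grid[which.max(di)]
  lo <- min(mode_a, mode_i)
  hi <- max(mode_a, mode_i)
  if (hi - lo <= 0) return(fallback())

  inside <- grid > lo & grid < hi
  idx <- which(inside)
  if (length(idx) < 2L) return(fallback())
  d <- da[idx] - di[idx]
  sign_change <- which(d[-length(d)] * d[-1] <= 0 &
                       !(d[-length(d)] == 0 & d[-1] == 0))
  if (!length(sign_change)) return(fallback())

  f <- function(x) kde_eval(a, x, bw_a) - kde_eval(i, x, bw_i)
  crossings <- vapply(sign_change, function(k) {
    x1 <- grid[idx[k]]
    x2 <- grid[idx[k + 1]]
    if (f(x1) == 0) return(x1)
    tryCatch(stats::uniroot(f, c(x1, x2), tol = 1e-10)$root,
             error = function(e) (x1 + x2) / 2)
  }, numeric(1))

  thr <- if (length(crossings) == 1L) crossings else {
    crossings[which.max(vapply(crossings, mcc_at, numeric(1)))]
  }
  structure(thr, method = "kde_crossing", orientation = orientation)
}

#' Impute missing docking / vote channels
#'
#' Completes the two scoring channels for a prediction set, in fixed order:
#' 1. a compound removed as a duplicate (salt stripped to the same parent,
#'    or a stereoisomer collapsing to the same canonical form) inherits the
#'    missing channel value(s) from its surviving parent via `duplicate_map`;
#' 2. a compound flagged as attempted-but-undocked (`docked = FALSE` in the
#'    docking table) receives a penalty score slightly worse than the worst
#'    observed raw score (worst + `penalty_offset`, default 0.02, matching
#'    the 2.78 -> 2.8 convention);
#' 3. anything still lacking a channel keeps NA; downstream classification
#'    reports it as `not_available`.
#'
#' @param ids character vector of compounds to complete.
#' @param duplicate_map data.frame `removed_id`, `kept_id` from
#'   [standardize_dataset()] (may be empty).
#' @param dock_table data.frame `id`, `dock_score`, and optionally `docked`
#'   (logical; FALSE marks attempted-but-undocked compounds).
#' @param vote_results data.frame `id`, `votes` from [predict_votes()].
#' @param penalty_offset added to the worst observed raw docking score for
#'   undocked compounds (default 0.02).
#' @return data.frame `id`, `dock_score`, `votes`, `note`.
#' @export
impute_missing <- function(ids, duplicate_map, dock_table, vote_results,
                           penalty_offset = 0.02) {
  ids <- as.character(ids)
  dup <- duplicate_map
  if (is.null(dup) || !nrow(dup)) {
    dup <- data.frame(removed_id = character(0), kept_id = character(0))
  }
  # resolve a removed id to its ultimate surviving parent; reject cycles
  resolve <- function(id) {
    seen <- character(0)
    while (id %in% dup$removed_id) {
      if (id %in% seen) vd_stop("cyclic duplicate_map at id '%s'", id)
      seen <- c(seen, id)
      id <- dup$kept_id[match(id, dup$removed_id)]
    }
    id
  }
  has_flag <- "docked" %in% names(dock_table)
  dock_of <- function(id) {
    k <- match(id, dock_table$id)
    if (is.na(k)) NA_real_ else dock_table$dock_score[k]
  }
  votes_of <- function(id) {
    k <- match(id, vote_results$id)
    if (is.na(k)) NA_real_ else vote_results$votes[k]
  }
  worst <- suppressWarnings(max(dock_table$dock_score, na.rm = TRUE))

  out <- lapply(ids, function(id) {
    note <- character(0)
    dk <- dock_of(id)
    vt <- votes_of(id)
    parent <- resolve(id)
    if (!identical(parent, id)) {
      if (is.na(dk)) {
        dk <- dock_of(parent)
        if (!is.na(dk)) note <- c(note, sprintf("dock_from_%s", parent))
      }
      if (is.na(vt)) {
        vt <- votes_of(parent)
        if (!is.na(vt)) note <- c(note, sprintf("votes_from_%s", parent))
      }
    }
    if (is.na(dk) && has_flag) {
      k <- match(id, dock_table$id)
      undocked <- !is.na(k) && isFALSE(dock_table$docked[k])
      if (undocked && is.finite(worst)) {
        dk <- worst + penalty_offset
        note <- c(note, "undocked_penalty")
      }
    }
    if (is.na(dk)) note <- c(note, "dock_missing")
    if (is.na(vt)) note <- c(note, "votes_missing")
    data.frame(id = id, dock_score = dk, votes = vt,
               note = paste(note, collapse = ";"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify compounds by consensus score
#'
#' Builds the per-compound consensus table: both normalized channels, their
#' sum, and the predicted label (active iff consensus strictly greater than
#' the threshold; `not_available` when a channel is missing).
#'
#' @param channels data.frame `id`, `dock_score`, `votes` (e.g. from
#'   [impute_missing()]); an optional `note` column is carried through.
#' @param threshold consensus decision threshold (default 0.82, the shipped
#'   KDE-derived value).
#' @param dock_bounds,vote_bounds normalization bounds.
#' @return data.frame `id`, `norm_dock`, `norm_votes`, `consensus`,
#'   `predicted_label`, `imputation_note`.
#' @export
classify_consensus <- function(channels, threshold = 0.82,
                               dock_bounds = votedock::dock_bounds(),
                               vote_bounds = votedock::vote_bounds()) {
  stopifnot(is.data.frame(channels),
            all(c("id", "dock_score", "votes") %in% names(channels)))
  norm_dock <- normalize_minmax(-channels$dock_score, dock_bounds)
  norm_votes <- normalize_minmax(channels$votes, vote_bounds)
  consensus <- norm_dock + norm_votes
  label <- ifelse(is.na(consensus), "not_available",
                  ifelse(consensus > threshold, "active", "inactive"))
  data.frame(id = channels$id, norm_dock = norm_dock,
             norm_votes = norm_votes, consensus = consensus,
             predicted_label = label,
             imputation_note = channels$note %||% "",
             stringsAsFactors = FALSE)
}

#' Binary label from a pChEMBL potency value
#'
#' Active iff `pchembl >= threshold` (inclusive: a pChEMBL of exactly 6 is
#' active at threshold 6, i.e. potency of 1 uM or better).
#'
#' @param pchembl numeric pChEMBL value(s) (-log10 molar potency).
#' @param threshold decision threshold; 6, 6.5 and 7 are the conventional
#'   choices.
#' @return character vector "active"/"inactive".
#' @export
pchembl_label <- function(pchembl, threshold = 6) {
  if (any(!is.finite(pchembl))) vd_stop("pchembl values must be finite")
  threshold <- assert_number(threshold, "threshold")
  ifelse(pchembl >= threshold, "active", "inactive")
}
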