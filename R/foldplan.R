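#' Plan outer cross-validation folds with within-fold undersampling
#'
#' Assigns every compound to one of `outer_k` stratified outer folds, then,
#' for each outer fold, partitions the inactives of its *training* portion
#' into `n_subsets` disjoint, size-balanced subsets and combines each subset
#' with the full set of training-fold actives. The result is `n_subsets`
#' approximately balanced training sets per outer fold, while validation
#' folds keep the original class imbalance.
#'
#' @param labels binary labels (0/1 or active/inactive) for all compounds.
#' @param outer_k number of outer folds (default 9).
#' @param n_subsets number of undersampled subsets per outer training fold
#'   (default 9; `1` disables undersampling and reproduces the plain
#'   baseline CV configuration).
#' @param seed integer seed; the plan is deterministic given labels + seed.
#' @return object of class `fold_plan`: `outer` (fold index per compound),
#'   `subsets` (list\[fold\]\[\[subset\]\] of compound indices), plus the
#'   arguments.
#' @export
make_fold_plan <- function(labels, outer_k = 9L, n_subsets = 9L, seed = 1L) {
  labels <- as_binary_labels(labels)
  outer_k <- assert_count(outer_k, "outer_k", min = 2L)
  n_subsets <- assert_count(n_subsets, "n_subsets")
  seed <- assert_count(seed, "seed", min = 0L)
  n <- length(labels)
  act <- which(labels == 1L)
  inact <- which(labels == 0L)
  if (!length(act) || !length(inact)) {
    vd_stop("both classes must be present (got %d actives, %d inactives)",
            length(act), length(inact))
  }

  outer <- integer(n)
  subsets <- vector("list", outer_k)
  with_seed(seed, {
    # stratified outer assignment: per-class round-robin over a shuffle keeps
    # every fold's active fraction within one compound of the global fraction
    outer[act] <- rep_len(seq_len(outer_k), length(act))[sample.int(length(act))]
    outer[inact] <- rep_len(seq_len(outer_k),
                            length(inact))[sample.int(length(inact))]

    for (f in seq_len(outer_k)) {
      tr <- which(outer != f)
      tr_act <- tr[labels[tr] == 1L]
      tr_inact <- tr[labels[tr] == 0L]
      if (n_subsets > 1L && length(tr_inact) < n_subsets) {
        vd_stop("outer training fold %d has %d inactives, fewer than %d subsets",
                f, length(tr_inact), n_subsets)
      }
      if (n_subsets == 1L) {
        subsets[[f]] <- list(sort(tr))  # baseline: the whole training fold
        next
      }
      shuffled <- sample(tr_inact)
      sizes <- balanced_part_sizes(length(tr_inact), n_subsets)
      ends <- cumsum(sizes)
      starts <- c(1L, head(ends, -1L) + 1L)
      subsets[[f]] <- lapply(seq_len(n_subsets), function(j) {
        sort(c(shuffled[starts[j]:ends[j]], tr_act))
      })
    }
  })
  structure(list(outer = outer, subsets = subsets, labels = labels,
                 outer_k = outer_k, n_subsets = n_subsets, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d compounds, %d outer folds, %d subsets/fold, seed %d\n",
              length(x$outer), x$outer_k, x$n_subsets, x$seed))
  invisible(x)
}

# Partition indices of inactives into n_subsets balanced subsets, each
# joined with all actives; used by retrain_final on the full training set.
undersample_subsets <- function(labels, n_subsets, seed) {
  labels <- as_binary_labels(labels)
  act <- which(labels == 1L)
  inact <- which(labels == 0L)
  if (n_subsets > 1L && length(inact) < n_subsets) {
    vd_stop("%d inactives cannot form %d subsets", length(inact), n_subsets)
  }
  if (n_subsets == 1L) return(list(seq_along(labels)))
  with_seed(seed, {
    shuffled <- sample(inact)
    sizes <- balanced_part_sizes(length(inact), n_subsets)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_len(n_subsets), function(j) {
      sort(c(shuffled[starts[j]:ends[j]], act))
    })
  })
}
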