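# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles and never call package internals.

# metrics straight from the textbook formulas
oracle_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    ba = (sens + spec) / 2,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0,
    precision = prec,
    recall = sens,
    f1 = if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  )
}

# AUC as the pairwise concordance probability, ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive all-pairs Tanimoto kNN, ties broken by reference order
oracle_knn <- function(qm, rm_, k) {
  out <- NULL
  for (qi in seq_len(nrow(qm))) {
    sims <- numeric(nrow(rm_))
    for (ri in seq_len(nrow(rm_))) {
      a <- qm[qi, ] != 0
      b <- rm_[ri, ] != 0
      un <- sum(a | b)
      sims[ri] <- if (un == 0) 1 else sum(a & b) / un
    }
    ord <- order(-sims, seq_along(sims))[seq_len(k)]
    out <- rbind(out, data.frame(query = qi, rank = seq_len(k),
                                 ref = ord, sim = sims[ord]))
  }
  out
}

random_fps <- function(n, bits, seed, p = 0.2) {
  set.seed(seed)
  matrix(rbinom(n * bits, 1, p), nrow = n)
}

# small separable dataset used by several CV tests
toy_separable <- function(n_per_class = 20, p = 4, gap = 6, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  y <- rep(c(1L, 0L), each = n_per_class)
  x[y == 1L, 1] <- x[y == 1L, 1] + gap
  list(x = x, y = y)
}
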