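#' Tanimoto k-nearest-neighbor applicability domain
#'
#' For every query compound, finds the `k` reference (model-building)
#' compounds with the highest Tanimoto fingerprint similarity. Exact search;
#' similarity ties are broken by reference order (first reference wins),
#' which makes the output independent of storage order up to that rule.
#'
#' @param query_fps binary [descriptor_matrix()] (or plain 0/1 matrix) of
#'   query compounds.
#' @param ref_fps binary descriptor matrix of reference compounds, same
#'   fingerprint width.
#' @param k neighbors per query (default 5); capped at the reference size.
#' @param ref_labels optional labels for the reference compounds, carried
#'   into the report.
#' @return data.frame `query_id`, `neighbor_rank`, `neighbor_id`, `tanimoto`
#'   and (if given) `neighbor_label`, sorted by query then rank.
#' @export
knn_tanimoto <- function(query_fps, ref_fps, k = 5L, ref_labels = NULL) {
  k <- assert_count(k, "k")
  qm <- if (inherits(query_fps, "descriptor_matrix")) query_fps$features else as.matrix(query_fps)
  rm_ <- if (inherits(ref_fps, "descriptor_matrix")) ref_fps$features else as.matrix(ref_fps)
  if (!nrow(rm_)) vd_stop("reference set is empty")
  if (ncol(qm) != ncol(rm_)) {
    vd_stop("fingerprint widths differ (query %d, reference %d)", ncol(qm),
            ncol(rm_))
  }
  qid <- rownames(qm) %||% sprintf("query_%d", seq_len(nrow(qm)))
  rid <- rownames(rm_) %||% sprintf("ref_%d", seq_len(nrow(rm_)))
  if (!is.null(ref_labels) && length(ref_labels) != nrow(rm_)) {
    vd_stop("ref_labels length != reference count")
  }
  k <- min(k, nrow(rm_))

  q <- (qm != 0) + 0
  r <- (rm_ != 0) + 0
  inter <- q %*% t(r)                                   # |a & b|
  uni <- outer(rowSums(q), rowSums(r), `+`) - inter     # |a | b|
  sim <- ifelse(uni == 0, 1, inter / uni)               # all-zero pair -> 1

  out <- lapply(seq_len(nrow(q)), function(qi) {
    ord <- order(-sim[qi, ], seq_len(ncol(sim)))[seq_len(k)]
    df <- data.frame(query_id = qid[qi], neighbor_rank = seq_len(k),
                     neighbor_id = rid[ord], tanimoto = sim[qi, ord],
                     stringsAsFactors = FALSE)
    if (!is.null(ref_labels)) df$neighbor_label <- ref_labels[ord]
    df
  })
  do.call(rbind, out)
}

#' Mean nearest-neighbor Tanimoto similarity
#'
#' Arithmetic mean over queries of each query's top-1 similarity; the
#' summary statistic used to judge whether a prediction set lies inside the
#' applicability domain of the model-building compounds.
#'
#' @param reports output of [knn_tanimoto()].
#' @return a single number in `[0, 1]`.
#' @export
mean_nn_similarity <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) > 0)
  top1 <- reports$tanimoto[reports$neighbor_rank == 1L]
  mean(top1)
}
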