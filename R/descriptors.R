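#' Descriptor matrix container
#'
#' Compounds-by-features matrix tagged as binary fingerprint or continuous
#' embedding. Binary matrices must contain only 0/1; no missing entries are
#' allowed in either kind.
#'
#' @param ids character vector of compound ids (row order).
#' @param features numeric matrix, `length(ids)` rows.
#' @param kind `"binary_fingerprint"` or `"continuous"`.
#' @return object of class `descriptor_matrix` with elements `ids`,
#'   `features`, `kind`, `width`.
#' @export
descriptor_matrix <- function(ids, features,
                              kind = c("continuous", "binary_fingerprint")) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (!is.character(ids)) ids <- as.character(ids)
  if (nrow(features) != length(ids)) {
    vd_stop("descriptor matrix has %d rows but %d ids", nrow(features),
            length(ids))
  }
  if (anyDuplicated(ids)) vd_stop("descriptor ids must be unique")
  if (anyNA(features)) vd_stop("descriptor matrix contains missing entries")
  if (kind == "binary_fingerprint" && !all(features %in% c(0, 1))) {
    vd_stop("binary fingerprint matrix contains entries outside {0,1}")
  }
  rownames(features) <- ids
  structure(list(ids = ids, features = features, kind = kind,
                 width = ncol(features)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d features (%s)\n",
              length(x$ids), x$width, x$kind))
  invisible(x)
}

#' ECFP4 fingerprints
#'
#' Folded circular (Morgan) fingerprints of radius 2, i.e. bond diameter 4,
#' computed with the RDKit backend.
#'
#' @param smiles character vector of standardized SMILES.
#' @param n_bits fingerprint length after folding (default 2048).
#' @param ids optional compound ids (default: the SMILES themselves).
#' @return a binary [descriptor_matrix()].
#' @export
ecfp4 <- function(smiles, n_bits = 2048L, ids = NULL) {
  n_bits <- assert_count(n_bits, "n_bits")
  ids <- ids %||% smiles
  res <- chem_tool("fingerprint",
                   data.frame(id = ids, smiles = smiles,
                              stringsAsFactors = FALSE),
                   args = c("--nbits", n_bits))
  bad <- res$id[res$bits == ""]
  if (length(bad)) {
    vd_stop("fingerprinting failed for unparseable structure(s): %s",
            paste(bad, collapse = ", "))
  }
  bits <- do.call(rbind, lapply(strsplit(res$bits, ""), as.integer))
  descriptor_matrix(res$id, bits, "binary_fingerprint")
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a & b| / |a | b|`; defined as 1 when both vectors are all-zero (two
#' featureless compounds are treated as identical).
#'
#' @param fp_a,fp_b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    vd_stop("fingerprint lengths differ (%d vs %d)", length(fp_a),
            length(fp_b))
  }
  a <- fp_a != 0
  b <- fp_b != 0
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Crippen atom-contribution logP
#'
#' @param smiles character vector of standardized SMILES.
#' @return numeric vector of logP values.
#' @export
crippen_logp <- function(smiles) {
  res <- chem_tool("logp",
                   data.frame(id = seq_along(smiles), smiles = smiles,
                              stringsAsFactors = FALSE))
  if (any(!is.finite(res$logp))) {
    vd_stop("logP failed for unparseable structure(s): %s",
            paste(smiles[!is.finite(res$logp)], collapse = ", "))
  }
  res$logp
}

#' Load a precomputed continuous descriptor table
#'
#' Reads a CSV with an `id` column followed by numeric feature columns
#' (e.g. CDDD embeddings exported from the pretrained encoder).
#'
#' @param path CSV file path.
#' @param ids optional id order to align to; ids in the table but not in
#'   `ids` are dropped with a warning, ids missing from the table raise an
#'   error.
#' @return a continuous [descriptor_matrix()].
#' @export
load_descriptor_table <- function(path, ids = NULL) {
  df <- read_table_csv(path)
  if (!"id" %in% names(df)) vd_stop("descriptor table needs an 'id' column")
  feat <- as.matrix(df[setdiff(names(df), "id")])
  storage.mode(feat) <- "double"
  if (anyNA(feat)) {
    bad <- df$id[rowSums(is.na(feat)) > 0]
    vd_stop("descriptor table has missing/non-numeric cells for: %s",
            paste(bad, collapse = ", "))
  }
  if (!is.null(ids)) {
    extra <- setdiff(df$id, ids)
    if (length(extra)) {
      vd_warn("descriptor table has %d id(s) absent from the compound set: %s",
              length(extra), paste(extra, collapse = ", "))
    }
    missing <- setdiff(ids, df$id)
    if (length(missing)) {
      vd_stop("descriptor table is missing id(s): %s",
              paste(missing, collapse = ", "))
    }
    df_order <- match(ids, df$id)
    feat <- feat[df_order, , drop = FALSE]
    return(descriptor_matrix(ids, feat, "continuous"))
  }
  descriptor_matrix(as.character(df$id), feat, "continuous")
}

#' Persist a descriptor matrix as CSV
#'
#' @param dm a [descriptor_matrix()].
#' @param path output CSV path.
#' @export
write_descriptor_table <- function(dm, path) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  df <- data.frame(id = dm$ids, dm$features, check.names = FALSE)
  write_table_csv(df, path)
}
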