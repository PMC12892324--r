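#' Standardize a single SMILES string
#'
#' Applies the fixed-order standardization pipeline: parse, keep the largest
#' fragment by heavy-atom count (salt stripping; ties broken by molecular
#' weight then canonical string), reject carbon-free (inorganic) species and
#' species with atoms outside the organic allowlist (metal), neutralize
#' charges where a proton can be added or removed (permanent cations such as
#' quaternary nitrogen are retained), remove all stereochemistry, and emit
#' the canonical form.
#'
#' @param smiles_raw a single non-empty SMILES string.
#' @return list with `smiles_std` (NA if rejected), `reject_reason` (one of
#'   "none", "inorganic", "metal", "parse_error") and `log` (semicolon-joined
#'   applied steps). Unparseable input yields `reject_reason = "parse_error"`,
#'   not an error.
#' @export
standardize_compound <- function(smiles_raw) {
  if (!is.character(smiles_raw) || length(smiles_raw) != 1L ||
      is.na(smiles_raw) || !nzchar(smiles_raw)) {
    vd_stop("smiles_raw must be a single non-empty string")
  }
  res <- standardize_smiles(smiles_raw)
  list(smiles_std = res$smiles_std, reject_reason = res$reject_reason,
       log = res$log)
}

# vectorized batch interface used internally and by standardize_dataset
standardize_smiles <- function(smiles) {
  df <- data.frame(id = sprintf("q%d", seq_along(smiles)), smiles = smiles,
                   stringsAsFactors = FALSE)
  out <- chem_tool("standardize", df)
  out <- out[match(df$id, out$id), ]
  data.frame(smiles_std = ifelse(out$reject_reason == "none", out$smiles_std,
                                 NA_character_),
             reject_reason = out$reject_reason, log = out$log,
             stringsAsFactors = FALSE)
}

#' Standardize a compound table and collapse duplicates
#'
#' Runs [standardize_compound()] over every record, then merges records whose
#' canonical forms coincide (e.g. enantiomers after stereochemistry removal,
#' or a salt and its free form). The first record in input order survives;
#' when merged duplicates carry conflicting activity labels the surviving
#' record is marked active (toxicology-conservative) and the conflict is
#' logged in `merge_note`.
#'
#' @param records data.frame with columns `id`, `smiles`, and optionally
#'   `label` (0/1 or active/inactive) and `cytotoxic` (logical).
#' @return list with:
#'   * `records`: kept records with `smiles_std`, `merged_from`
#'     (semicolon-joined ids), `merge_note`;
#'   * `rejected`: rejected records with `reject_reason`;
#'   * `duplicate_map`: data.frame `removed_id` -> `kept_id`;
#'   * `report`: counts (`input`, `kept`, `rejected`, `merged`) partitioning
#'     the input exactly.
#' @export
standardize_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("id", "smiles") %in% names(records))) {
    vd_stop("records need 'id' and 'smiles' columns")
  }
  if (anyDuplicated(records$id)) {
    vd_stop("duplicate input ids: %s",
            paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  records$id <- as.character(records$id)
  n <- nrow(records)
  if (n == 0L) {
    empty <- data.frame(id = character(0), smiles = character(0))
    return(list(records = cbind(empty, smiles_std = character(0),
                                merged_from = character(0),
                                merge_note = character(0)),
                rejected = cbind(empty, reject_reason = character(0)),
                duplicate_map = data.frame(removed_id = character(0),
                                           kept_id = character(0)),
                report = list(input = 0L, kept = 0L, rejected = 0L,
                              merged = 0L)))
  }
  if (!"label" %in% names(records)) records$label <- NA
  if (!"cytotoxic" %in% names(records)) records$cytotoxic <- FALSE

  std <- standardize_smiles(records$smiles)
  rejected <- cbind(records[std$reject_reason != "none", , drop = FALSE],
                    reject_reason = std$reject_reason[std$reject_reason != "none"])
  ok <- which(std$reject_reason == "none")
  kept_rows <- list()
  dup_removed <- character(0)
  dup_kept <- character(0)
  canon_seen <- character(0)
  canon_row <- integer(0)

  lab <- if (all(is.na(records$label))) rep(NA_integer_, n) else {
    as_binary_labels(ifelse(is.na(records$label), 0, records$label))
  }
  merged_from <- setNames(rep("", n), records$id)
  merge_note <- setNames(rep("", n), records$id)
  surviving <- integer(0)

  for (i in ok) {
    smi <- std$smiles_std[i]
    hit <- match(smi, canon_seen)
    if (is.na(hit)) {
      canon_seen <- c(canon_seen, smi)
      canon_row <- c(canon_row, i)
      surviving <- c(surviving, i)
    } else {
      keeper <- canon_row[hit]
      dup_removed <- c(dup_removed, records$id[i])
      dup_kept <- c(dup_kept, records$id[keeper])
      merged_from[keeper] <- paste0(merged_from[keeper],
                                    if (nzchar(merged_from[keeper])) ";",
                                    records$id[i])
      if (!is.na(lab[i]) && !is.na(lab[keeper]) && lab[i] != lab[keeper]) {
        lab[keeper] <- 1L  # conflicting duplicate labels: keep active
        merge_note[keeper] <- paste0(
          merge_note[keeper], if (nzchar(merge_note[keeper])) ";",
          sprintf("label_conflict_with_%s_kept_active", records$id[i]))
      }
    }
  }

  kept <- records[surviving, , drop = FALSE]
  kept$label <- lab[surviving]
  kept$smiles_std <- std$smiles_std[surviving]
  kept$merged_from <- unname(merged_from[surviving])
  kept$merge_note <- unname(merge_note[surviving])

  report <- list(input = n, kept = nrow(kept), rejected = nrow(rejected),
                 merged = length(dup_removed))
  stopifnot(report$kept + report$rejected + report$merged == report$input)
  list(records = kept, rejected = rejected,
       duplicate_map = data.frame(removed_id = dup_removed,
                                  kept_id = dup_kept,
                                  stringsAsFactors = FALSE),
       report = report)
}

#' Read a compound table from CSV or SDF
#'
#' CSV must have `id` and `smiles` columns (plus optional `label`,
#' `cytotoxic`); SDF records are converted through the RDKit backend, with
#' molecule names used as ids (falling back to `sdf_<n>`).
#'
#' @param path input file; format chosen by extension (.sdf vs anything else).
#' @return data.frame with at least `id` and `smiles`.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) vd_stop("input file not found: %s", path)
  if (tolower(tools::file_ext(path)) == "sdf") {
    out <- chem_tool("sdf_to_csv", NULL, input_path = path)
    out$id <- as.character(out$id)
    return(out)
  }
  df <- read_table_csv(path)
  if (!all(c("id", "smiles") %in% names(df))) {
    vd_stop("compound CSV needs 'id' and 'smiles' columns: %s", path)
  }
  df$id <- as.character(df$id)
  df
}

#' Write standardization outputs
#'
#' @param std result of [standardize_dataset()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_standardized <- function(std, dir) {
  paths <- list(records = file.path(dir, "standardized.csv"),
                rejected = file.path(dir, "rejected.csv"),
                duplicate_map = file.path(dir, "duplicate_map.csv"))
  write_table_csv(std$records, paths$records)
  write_table_csv(std$rejected, paths$rejected)
  write_table_csv(std$duplicate_map, paths$duplicate_map)
  invisible(paths)
}
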