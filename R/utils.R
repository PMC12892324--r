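# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vd_stop <- function(...) stop(sprintf(...), call. = FALSE)
vd_warn <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    vd_stop("'%s' must be a single integer >= %d (got %s)", name, min,
            paste(format(x), collapse = ","))
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    vd_stop("'%s' must be a single finite number", name)
  }
  if (strict && x <= min) vd_stop("'%s' must be > %g", name, min)
  if (!strict && x < min) vd_stop("'%s' must be >= %g", name, min)
  as.numeric(x)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Split n items into k parts whose sizes differ by at most one,
# larger parts first: 1048 over 9 -> 117 117 117 117 116 116 116 116 116.
balanced_part_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
}

#' Stratified training / test split
#'
#' Splits binary labels into a training and test partition, sampling the
#' requested fraction within each class (the 80/20 stratified split used by
#' the pipeline).
#'
#' @param labels binary labels (0/1 or active/inactive).
#' @param train_frac fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return logical vector: `TRUE` = training set member.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  labels <- as_binary_labels(labels)
  in_train <- logical(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      n_tr <- round(length(idx) * train_frac)
      in_train[sample(idx, n_tr)] <- TRUE
    }
  })
  in_train
}

# Coerce assorted label encodings to integer 0/1.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    out <- ifelse(labels %in% c("active", "1"), 1L,
                  ifelse(labels %in% c("inactive", "0"), 0L, NA_integer_))
  } else {
    out <- as.integer(labels)
  }
  if (anyNA(out) || !all(out %in% c(0L, 1L))) {
    vd_stop("labels must be binary (0/1 or active/inactive)")
  }
  out
}

read_table_csv <- function(path) {
  if (!file.exists(path)) vd_stop("input file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_table_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
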