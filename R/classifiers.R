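# Thin R wrappers around the compiled base learners (src/classifiers.cpp).
# One common interface so the CV engine is algorithm-agnostic:
#   fit_classifier(X, y, algorithm, params, seed) -> "votedock_classifier"
#   predict(model, X)                             -> integer 0/1 votes

#' Default hyperparameters per algorithm
#'
#' Conventional library defaults: RF 100 trees, unlimited depth, sqrt(p)
#' features per split; SVM C = 1 with an RBF kernel and "scale" gamma;
#' gradient boosting 100 rounds, depth 6, learning rate 0.3, L2 lambda 1.
#'
#' @param algorithm "RF", "SVM" or "XGB".
#' @return named list of parameters.
#' @export
default_params <- function(algorithm = c("RF", "SVM", "XGB")) {
  switch(match.arg(algorithm),
         RF = list(n_estimators = 100L, max_depth = NA),
         SVM = list(C = 1, kernel = "rbf"),
         XGB = list(n_estimators = 100L, max_depth = 6L))
}

#' Fit a binary classifier
#'
#' @param X numeric matrix (compounds x features).
#' @param y binary labels (0/1 or active/inactive).
#' @param algorithm "RF", "SVM" or "XGB".
#' @param params named list; unspecified entries fall back to
#'   [default_params()]. RF: `n_estimators`, `max_depth` (NA = unlimited).
#'   SVM: `C`, `kernel` ("linear"/"rbf"). XGB: `n_estimators`, `max_depth`.
#' @param seed integer seed for the learner's internal randomness.
#' @return object of class `votedock_classifier`.
#' @export
fit_classifier <- function(X, y, algorithm = c("RF", "SVM", "XGB"),
                           params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) vd_stop("X rows (%d) != labels (%d)", nrow(X),
                                    length(y))
  if (length(unique(y)) < 2L) vd_stop("training data contains a single class")
  params <- modifyList(default_params(algorithm), params)
  seed <- assert_count(seed, "seed", min = 0L)

  fit <- switch(algorithm,
    RF = {
      depth <- params$max_depth
      depth <- if (is.null(depth) || is.na(depth)) 0L else as.integer(depth)
      mtry <- max(1L, floor(sqrt(ncol(X))))
      list(trees = .fit_forest_cpp(X, y, as.integer(params$n_estimators),
                                   depth, mtry, seed))
    },
    SVM = {
      kernel_id <- match(params$kernel, c("linear", "rbf")) - 1L
      if (is.na(kernel_id)) vd_stop("unknown SVM kernel '%s'", params$kernel)
      # sklearn's gamma="scale": 1 / (p * Var(X)) over all matrix entries
      v <- mean(X^2) - mean(X)^2
      gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
      ysvm <- ifelse(y == 1L, 1, -1)
      m <- .fit_svm_cpp(X, ysvm, as.numeric(params$C), kernel_id, gamma,
                        1e-3, 5L, seed)
      c(m, list(kernel_id = kernel_id, gamma = gamma))
    },
    XGB = list(trees = .fit_xgb_cpp(X, y, as.integer(params$n_estimators),
                                    as.integer(params$max_depth),
                                    0.3, 1.0, 1.0)))

  structure(list(algorithm = algorithm, params = params, fit = fit,
                 width = ncol(X), seed = seed),
            class = "votedock_classifier")
}

#' Predict binary votes from a fitted classifier
#'
#' @param object a `votedock_classifier`.
#' @param newdata numeric matrix with the training width.
#' @param type `"vote"` for 0/1 labels, `"decision"` for the raw decision
#'   value (RF: active-class probability; SVM: decision function; XGB: logit).
#' @param ... unused.
#' @return integer votes or numeric decision values.
#' @export
predict.votedock_classifier <- function(object, newdata,
                                        type = c("vote", "decision"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$width) {
    vd_stop("feature width %d does not match training width %d", ncol(X),
            object$width)
  }
  dec <- switch(object$algorithm,
                RF = .predict_forest_cpp(object$fit$trees, X),
                SVM = .predict_svm_cpp(object$fit$sv, object$fit$coef,
                                       object$fit$b, object$fit$kernel_id,
                                       object$fit$gamma, X),
                XGB = .predict_xgb_cpp(object$fit$trees, X))
  if (type == "decision") return(dec)
  cut <- switch(object$algorithm, RF = 0.5, SVM = 0, XGB = 0)
  as.integer(dec > cut)
}

#' @export
print.votedock_classifier <- function(x, ...) {
  cat(sprintf("<votedock_classifier> %s (%s)\n", x$algorithm,
              paste(names(x$params), unlist(lapply(x$params, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
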