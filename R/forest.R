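#' Random-forest classifier (bundled implementation)
#'
#' A compact classification forest used by the screening and diagnostic
#' modules: bootstrap resampling, CART trees with Gini splits, `sqrt(p)`
#' candidate features per node, out-of-bag (OOB) error, OOB permutation
#' importance (unscaled mean decrease in accuracy) and Gini importance.
#' Fully deterministic for a given seed.
#'
#' @param X numeric feature matrix (samples x features) with column names.
#' @param y binary labels (0 = control, 1 = case) or a two-level factor.
#' @param n_trees number of trees (default 1000).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param min_node minimum node size to attempt a split (default 1, i.e.
#'   trees are grown to purity as usual for classification).
#' @param seed integer seed.
#' @param importance compute permutation importance (slightly slower).
#' @return List of class `gutpod_rf`: `trees`, `oob_votes` (OOB fraction of
#'   trees voting class 1, per training sample), `oob_error`, `importance`
#'   (data.frame feature/mda/gini, descending mda), `params`.
#' @export
rf_fit <- function(X, y, n_trees = 1000, mtry = NULL, min_node = 1,
                   seed = 1, importance = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.factor(y) || is.character(y)) y <- as_binary_labels(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fit <- .rf_fit_cpp(X, y, as.integer(n_trees), as.integer(mtry),
                     as.integer(min_node), as.numeric(derive_seed(seed, "rf")),
                     isTRUE(importance))
  imp <- data.frame(feature = colnames(X), mda = fit$mda, gini = fit$gini,
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mda, imp$feature), ]
  rownames(imp) <- NULL
  structure(list(trees = fit$trees,
                 oob_votes = setNames(fit$oob_votes, rownames(X)),
                 oob_error = fit$oob_error, importance = imp,
                 features = colnames(X),
                 params = list(n_trees = n_trees, mtry = mtry,
                               min_node = min_node, seed = seed)),
            class = "gutpod_rf")
}

#' Predict disease-vote fractions from a fitted forest
#'
#' @param object a `gutpod_rf` fit.
#' @param newdata matrix with (at least) the training features as columns.
#' @param ... unused.
#' @return Named numeric vector: fraction of trees voting class 1.
#' @export
predict.gutpod_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("features absent from newdata: ", paste(missing, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  setNames(.rf_predict_cpp(object$trees, X), rownames(newdata))
}

#' @export
print.gutpod_rf <- function(x, ...) {
  cat(sprintf("random forest: %d trees, mtry %d, %d features, OOB error %.3f\n",
              x$params$n_trees, x$params$mtry, length(x$features),
              x$oob_error))
  invisible(x)
}
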