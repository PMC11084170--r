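# R interface to the compiled regression forest.

#' Fit a regression random forest
#'
#' Bootstrap-aggregated CART regression trees with variance-reduction
#' splits and per-node feature subsampling, implemented in C++ and
#' deterministic for a given seed. Predictions are averages of leaf means,
#' so they always lie within the training response range.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Numeric response (age in years).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `max(floor(sqrt(p)), 1)`.
#' @param max_depth Maximum tree depth; `Inf` for unbounded.
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param seed Integer seed.
#' @return Object of class `wsh_rf` holding the trees, per-feature impurity
#'   importances (named by column), and the fit parameters.
#' @export
rf_fit <- function(X, y, n_trees = 500L, mtry = NULL, max_depth = Inf,
                   min_leaf = 1L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(mtry)) mtry <- max(floor(sqrt(ncol(X))), 1L)
  md <- if (is.infinite(max_depth)) -1L else as.integer(max_depth)
  fit <- .rf_fit_cpp(X, as.numeric(y), as.integer(n_trees), as.integer(mtry),
                     md, as.integer(min_leaf), as.integer(seed))
  imp <- fit$importance
  names(imp) <- colnames(X)
  structure(list(trees = fit$trees, importance = imp,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 max_depth = max_depth, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed), features = colnames(X),
                 y_range = range(y)),
            class = "wsh_rf")
}

#' Predict from a fitted regression forest
#'
#' @param object A `wsh_rf` model.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param n_trees Use only the first `n_trees` trees (the prefix of a
#'   forest is itself a valid smaller forest); default all.
#' @param ... Unused.
#' @export
predict.wsh_rf <- function(object, newdata, n_trees = NULL, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(object$features)) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  .rf_predict_cpp(object$trees, newdata,
                  if (is.null(n_trees)) -1L else as.integer(n_trees))
}
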