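#' Regression random forest
#'
#' A compact regression random forest: CART variance-reduction splits,
#' bootstrap resampling of observations, `mtry` feature subsampling at each
#' node, and impurity (SSE-decrease) variable importance. It is the learner
#' behind [rfe_select()]; the defaults (500 trees, `mtry = p/3`, minimum node
#' size 5) follow long-standing regression-forest practice.
#'
#' Randomness comes from R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param X numeric matrix of predictors (rows = observations)
#' @param y numeric response
#' @param ntree number of trees
#' @param mtry features tried per split; default `max(1, floor(p / 3))`
#' @param min_node nodes of this size or smaller are not split
#' @return A `random_forest` object with `$importance` (named, per feature)
#'   and a [predict][predict.random_forest] method.
#' @export
random_forest <- function(X, y, ntree = 500, mtry = NULL, min_node = 5) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ntree >= 1)
  if (anyNA(X) || anyNA(y)) stop("random_forest: missing values not supported")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  fit <- rf_build(X, as.numeric(y), as.integer(ntree), as.integer(mtry),
                  as.integer(min_node))
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X)
  structure(list(trees = fit$trees, importance = imp, ntree = ntree,
                 mtry = mtry, min_node = min_node,
                 features = colnames(X)),
            class = "random_forest")
}

#' Predict from a regression random forest
#'
#' @param object a [random_forest()] fit
#' @param newdata matrix with the same columns (by name if named) as training
#' @param ... unused
#' @return Numeric vector of predictions (mean over trees).
#' @export
predict.random_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    if (!all(object$features %in% colnames(newdata))) {
      stop("predict.random_forest: newdata lacks training features")
    }
    newdata <- newdata[, object$features, drop = FALSE]
  }
  as.numeric(rf_predict_cpp(object$trees, newdata))
}
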