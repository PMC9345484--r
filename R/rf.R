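## R-side interface to the C++ random forest.

#' Random forest binary classifier
#'
#' CART trees (Gini impurity) grown on bootstrap samples with per-node
#' random feature subsampling. Defaults are pinned to the common toolkit
#' defaults so "default set of parameters" is reproducible: 100 trees,
#' `mtry = floor(sqrt(p))`, unlimited depth, `min_split = 2`. Randomness is
#' drawn from R's RNG: call `set.seed()` (or use the modeling wrappers,
#' which do) for reproducible forests.
#'
#' @param X numeric matrix, rows = observations.
#' @param y labels: a factor, character or 0/1 vector with two levels. The
#'   positive class is the second level of `factor(y)` (or `1` for a numeric
#'   0/1 vector).
#' @param n_trees number of trees (default 100).
#' @param mtry features tried per split (default `floor(sqrt(p))`, min 1).
#' @param max_depth maximal tree depth; `0` or `Inf` means unlimited.
#' @param min_split minimal node size to attempt a split (default 2).
#' @return object of class `oc_rf`.
#' @export
random_forest <- function(X, y, n_trees = 100L, mtry = NULL, max_depth = 0L,
                          min_split = 2L) {
  X <- as.matrix(X)
  yb <- binarize_labels(y)
  if (length(unique(yb)) < 2L) stop("both classes must be present")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  if (!is.finite(max_depth)) max_depth <- 0L
  forest <- cpp_grow_forest(X, as.integer(yb), as.integer(n_trees), mtry,
                            as.integer(max_depth), as.integer(min_split))
  structure(list(forest = forest, n_trees = n_trees, mtry = mtry,
                 max_depth = max_depth, levels = attr(yb, "levels")),
            class = "oc_rf")
}

#' @export
print.oc_rf <- function(x, ...) {
  cat("<oc_rf>", x$n_trees, "trees, mtry", x$mtry, ", max depth",
      if (x$max_depth == 0) "unlimited" else x$max_depth, "\n")
  invisible(x)
}

#' @param object an `oc_rf` model.
#' @param newdata numeric matrix of observations to score.
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @rdname random_forest
#' @export
predict.oc_rf <- function(object, newdata, ...) {
  cpp_predict_forest(object$forest, as.matrix(newdata))
}

## map labels to 0/1 with attribute `levels` = c(negative, positive)
binarize_labels <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1)))
    return(structure(as.integer(y), levels = c("0", "1")))
  f <- factor(y)
  if (nlevels(f) > 2L) stop("binary labels required")
  structure(as.integer(f) - 1L, levels = levels(f))
}
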