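#' Fit a random forest (internal imputation engine)
#'
#' A compact CART forest (bootstrap + random feature subsets, exact split
#' search) used by the iterative imputer: regression trees split on variance
#' reduction, classification trees on Gini. Not a general-purpose forest —
#' predictors must already be numeric (categoricals one-hot encoded).
#'
#' @param X numeric matrix of predictors.
#' @param y numeric vector (regression) or factor (classification).
#' @param ntree number of trees.
#' @param mtry features tried per split; defaults to `p/3` (regression) or
#'   `sqrt(p)` (classification).
#' @param min_node minimum observations per leaf.
#' @param max_depth maximum tree depth.
#' @param seed integer seed; forests are deterministic given it.
#' @return a `tte_forest`.
#' @keywords internal
rf_fit <- function(X, y, ntree = 100, mtry = NULL, min_node = 5,
                   max_depth = 25, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  classify <- is.factor(y)
  if (classify) {
    levs <- levels(y)
    yy <- as.numeric(y) - 1
    nclass <- length(levs)
  } else {
    levs <- NULL
    yy <- as.numeric(y)
    nclass <- 1L
  }
  p <- ncol(X)
  # floors of 3 (regression) / 2 (classification) matter for the small
  # covariate tables typical here, where one-hot expansion leaves only a
  # handful of predictors and tiny mtry would starve the informative one
  if (is.null(mtry))
    mtry <- min(p, if (classify) max(2L, ceiling(sqrt(p)))
                else max(3L, ceiling(p / 3)))
  trees <- .cart_forest_fit(X, yy, classify, nclass, as.integer(ntree),
                            as.integer(mtry), as.integer(min_node),
                            as.integer(max_depth), as.integer(seed))
  structure(list(trees = trees, classify = classify, levels = levs, p = p),
            class = "tte_forest")
}

#' @rdname rf_fit
#' @param forest a fitted `tte_forest`.
#' @keywords internal
rf_predict <- function(forest, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(ncol(X) == forest$p)
  out <- .cart_forest_predict(forest$trees, X, forest$classify,
                              if (forest$classify) length(forest$levels) else 1L)
  if (forest$classify) {
    # ties in averaged class proportions break to the lowest level index
    factor(forest$levels[apply(out, 1, which.max)], levels = forest$levels)
  } else {
    out[, 1]
  }
}
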