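#' Fit a random forest on PT5-expanded training examples
#'
#' Grows `ntree` un-pruned classification trees (via \pkg{ranger}) on
#' bootstrap resamples of the single-label examples, sampling `mtry`
#' features at each split. The terminal-node assignment of every training
#' row in every tree is stored so that proximities can be recomputed and
#' audited directly.
#'
#' @param train a `pt5_df` from [pt5_transform()] (or [ml_dataset()], which
#'   is transformed first).
#' @param ntree number of trees.
#' @param mtry features sampled per split; default `floor(sqrt(M))`.
#' @param seed integer seed driving bootstrap and feature sampling.
#' @return An object of class `cp_forest`: the fitted forest plus the
#'   `ntree x n'` leaf assignments (stored transposed as `n' x ntree`),
#'   labels, origins and feature names.
#' @examples
#' d <- simulate_cf_dataset(15, m = 12, signature_size = 3, seed = 1)
#' f <- fit_forest(pt5_transform(d), ntree = 50, seed = 1)
#' glance(f)
#' @export
fit_forest <- function(train, ntree = 1000, mtry = NULL, seed = 1L) {
  if (inherits(train, "ml_dataset")) train <- pt5_transform(train)
  stopifnot(inherits(train, "pt5_df"))
  X <- ml_features(train)
  labels <- train$label
  if (nrow(X) < 2L) {
    abort("degenerate training set: need at least two rows",
          class = "mlcp_fit_error")
  }
  const_x <- all(apply(X, 2L, function(v) length(unique(v)) == 1L))
  if (const_x && length(unique(labels)) == 1L) {
    abort("degenerate training set: constant features and constant labels",
          class = "mlcp_fit_error")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (mtry > ncol(X)) abort("mtry exceeds the feature count")
  xdf <- as.data.frame(X)
  fit <- ranger::ranger(x = xdf, y = factor(labels),
                        num.trees = ntree, mtry = mtry,
                        min.node.size = 1L, num.threads = 1L,
                        seed = as.integer(seed))
  nodes <- stats::predict(fit, xdf, type = "terminalNodes",
                          num.threads = 1L)$predictions
  structure(list(forest = fit, ntree = ntree, mtry = mtry, seed = seed,
                 nodes = nodes, labels = labels, origin = train$origin,
                 feature_cols = attr(train, "feature_cols"),
                 alphabet = ml_alphabet(train)),
            class = "cp_forest")
}

#' @export
print.cp_forest <- function(x, ...) {
  cat(sprintf("<cp_forest> %d trees, mtry %d, %d examples, %d labels\n",
              x$ntree, x$mtry, nrow(x$nodes), length(unique(x$labels))))
  invisible(x)
}

#' @method glance cp_forest
#' @export
glance.cp_forest <- function(x, ...) {
  tibble::tibble(ntree = x$ntree, mtry = x$mtry, n_examples = nrow(x$nodes),
                 n_labels = length(unique(x$labels)),
                 oob_error = x$forest$prediction.error, seed = x$seed)
}

#' Random-forest proximities
#'
#' The proximity of two examples is the fraction of trees in which both land
#' in the same terminal node: a data-adaptive similarity in `[0, 1]` with
#' unit diagonal. If `newdata` is supplied, each new row is dropped down
#' every tree and its proximity vector to all training rows is returned as
#' well.
#'
#' @param forest a [fit_forest()] model.
#' @param newdata optional feature matrix / data frame of test instances.
#' @return A list with `values` (symmetric n' x n' matrix) and `test_rows`
#'   (`NULL`, or an n_test x n' matrix of test-to-train proximities).
#' @export
forest_proximity <- function(forest, newdata = NULL) {
  stopifnot(inherits(forest, "cp_forest"))
  values <- proximity_from_nodes(forest$nodes)
  test_rows <- NULL
  if (!is.null(newdata)) {
    nd <- as.data.frame(as.matrix(newdata))
    if (ncol(nd) != length(forest$feature_cols)) {
      abort("test instance has the wrong number of features",
            class = "mlcp_shape_error")
    }
    colnames(nd) <- forest$feature_cols
    tn <- stats::predict(forest$forest, nd, type = "terminalNodes",
                         num.threads = 1L)$predictions
    test_rows <- test_proximity_from_nodes(forest$nodes, tn)
  }
  list(values = values, test_rows = test_rows)
}

# co-terminal-node counts over trees via a sparse row-by-(tree,node)
# indicator; equivalent to looping over trees and counting matches
proximity_from_nodes <- function(nodes) {
  n <- nrow(nodes)
  ntree <- ncol(nodes)
  key <- factor(paste(rep(seq_len(ntree), each = n), as.vector(nodes),
                      sep = "."))
  S <- Matrix::sparseMatrix(i = rep(seq_len(n), ntree),
                            j = as.integer(key), x = 1)
  as.matrix(Matrix::tcrossprod(S)) / ntree
}

test_proximity_from_nodes <- function(train_nodes, test_nodes) {
  n <- nrow(train_nodes)
  out <- matrix(0, nrow(test_nodes), n)
  for (i in seq_len(nrow(test_nodes))) {
    out[i, ] <- rowMeans(train_nodes ==
                           matrix(test_nodes[i, ], n, ncol(train_nodes),
                                  byrow = TRUE))
  }
  out
}
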