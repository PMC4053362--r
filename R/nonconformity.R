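#' Nonconformity scores for conformal prediction
#'
#' A nonconformity score measures how unusual an example is relative to a
#' bag of single-label training examples: large alpha = nonconforming. Three
#' scorers are provided.
#'
#' `rf_nonconformity()` is the random-forest proximity ratio: with `prox`
#' the proximities between the evaluated example and the training rows,
#' alpha = (sum of the K largest proximities to rows labelled *differently*)
#' / (sum of the K largest proximities to rows with the *same* label). An
#' example deep inside its own class has large same-label proximities, hence
#' small alpha.
#'
#' `knn_nonconformity()` is the classical distance ratio: alpha = (sum of
#' the K smallest Euclidean distances to same-label rows) / (sum of the K
#' smallest distances to different-label rows).
#'
#' `nbc_nonconformity()` is one minus the Bernoulli naive-Bayes posterior of
#' the evaluated label (Laplace smoothing `smoothing`).
#'
#' All scorers exclude `exclude` rows (the example itself and, under PT5,
#' every replicate sharing its origin case) from both candidate pools:
#' a case's own replicates have identical features (proximity 1, distance 0)
#' and would otherwise corrupt the different-label pool. Pools with fewer
#' than K members use all they have. An empty same-label pool yields
#' `Inf` (maximally nonconforming), an empty different-label pool yields 0;
#' a 0/0 ratio is defined as 1 (no evidence either way). Ties when picking
#' the K largest/smallest are broken by row index, ascending.
#'
#' @param prox numeric vector of proximities from the evaluated example to
#'   every training row.
#' @param labels character vector of training row labels, aligned with
#'   `prox` / `dist` / the rows of the naive-Bayes model.
#' @param label the candidate label under evaluation.
#' @param K number of neighbours entering each pool sum.
#' @param exclude integer indices of rows to drop from both pools.
#' @return A single non-negative number (possibly `Inf`).
#' @examples
#' rf_nonconformity(c(1, .9, .2, .1), c("A", "A", "B", "B"), "A", K = 2)
#' @export
rf_nonconformity <- function(prox, labels, label, K = 1L, exclude = integer()) {
  pool_ratio(prox, labels, label, K, exclude, largest = TRUE,
             num_same = FALSE)
}

#' @rdname rf_nonconformity
#' @param dist numeric vector of distances from the evaluated example to
#'   every training row.
#' @export
knn_nonconformity <- function(dist, labels, label, K = 1L, exclude = integer()) {
  pool_ratio(dist, labels, label, K, exclude, largest = FALSE,
             num_same = TRUE)
}

# shared top-K two-pool ratio.
# largest: pick K largest values (proximities) vs K smallest (distances).
# num_same: same-label pool in the numerator (distances) or denominator
# (proximities); either way small alpha = conforming.
pool_ratio <- function(values, labels, label, K, exclude, largest, num_same) {
  stopifnot(K >= 1L, length(values) == length(labels))
  keep <- setdiff(seq_along(values), exclude)
  same <- keep[labels[keep] == label]
  diff <- keep[labels[keep] != label]
  if (length(same) == 0L) return(Inf)
  if (length(diff) == 0L) return(0)
  top <- function(idx) {
    ord <- if (largest) order(-values[idx], idx) else order(values[idx], idx)
    sum(values[idx[ord[seq_len(min(K, length(idx)))]]])
  }
  s_same <- top(same)
  s_diff <- top(diff)
  num <- if (num_same) s_same else s_diff
  den <- if (num_same) s_diff else s_same
  if (den == 0) {
    if (num == 0) 1 else Inf
  } else {
    num / den
  }
}

#' @rdname rf_nonconformity
#' @param model a Bernoulli naive-Bayes fit from [fit_nbc()].
#' @param x binary feature vector of the evaluated example.
#' @export
nbc_nonconformity <- function(model, x, label) {
  post <- nbc_posterior(model, x)
  if (!label %in% names(post)) {
    abort(paste0("label not in the model's alphabet: ", label))
  }
  1 - post[[label]]
}

#' Bernoulli naive Bayes on binary features
#'
#' Smoothed class priors `(count + s) / (n + s q)` and per-feature firing
#' probabilities `(count + s) / (class count + 2 s)`. Every alphabet label
#' gets a class even when unobserved, so posteriors stay strictly inside
#' (0, 1). `nbc_drop_rows()` removes rows from the sufficient statistics
#' (used to score a PT5 training row against a model that has never seen its
#' origin case).
#'
#' @param X binary feature matrix of single-label training rows.
#' @param labels their labels.
#' @param alphabet full ordered label alphabet.
#' @param smoothing Laplace constant s > 0.
#' @return An object of class `nbc_model` holding the counts.
#' @keywords internal
#' @export
fit_nbc <- function(X, labels, alphabet = sort(unique(labels)),
                    smoothing = 1) {
  stopifnot(smoothing > 0)
  X <- as.matrix(X)
  counts <- vapply(alphabet, function(a) sum(labels == a), numeric(1L))
  feat1 <- t(vapply(alphabet,
                    function(a) colSums(X[labels == a, , drop = FALSE]),
                    numeric(ncol(X))))
  rownames(feat1) <- alphabet
  structure(list(alphabet = alphabet, counts = counts, feat1 = feat1,
                 n = nrow(X), smoothing = smoothing),
            class = "nbc_model")
}

#' @rdname fit_nbc
#' @param model an `nbc_model`.
#' @param rows_X feature rows to remove; `rows_labels` their labels.
#' @keywords internal
#' @export
nbc_drop_rows <- function(model, rows_X, rows_labels) {
  rows_X <- matrix(rows_X, ncol = ncol(model$feat1))
  for (i in seq_along(rows_labels)) {
    a <- rows_labels[i]
    model$counts[[a]] <- model$counts[[a]] - 1
    model$feat1[a, ] <- model$feat1[a, ] - rows_X[i, ]
  }
  model$n <- model$n - length(rows_labels)
  model
}

#' @rdname fit_nbc
#' @param x a single binary feature vector.
#' @keywords internal
#' @export
nbc_posterior <- function(model, x) {
  s <- model$smoothing
  q <- length(model$alphabet)
  logp <- vapply(model$alphabet, function(a) {
    prior <- (model$counts[[a]] + s) / (model$n + s * q)
    p1 <- (model$feat1[a, ] + s) / (model$counts[[a]] + 2 * s)
    log(prior) + sum(x * log(p1) + (1 - x) * log1p(-p1))
  }, numeric(1L))
  w <- exp(logp - max(logp))
  setNames(w / sum(w), model$alphabet)
}
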