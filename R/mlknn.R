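#' ML-KNN: multi-label K-nearest-neighbour baseline
#'
#' The classical ML-KNN comparator. For each label, a Bernoulli prior
#' `P(label) = (s + #cases with label) / (2s + n)` and neighbour-count
#' likelihoods `P(j of K neighbours carry the label | label present/absent)`
#' are estimated from leave-one-out neighbour statistics on the training
#' cases with Laplace smoothing `s`. At prediction time the posterior of
#' each label given the observed neighbour count is computed by Bayes'
#' rule and labels above a probability threshold form the region.
#'
#' @param data an [ml_dataset()].
#' @param K neighbour count (`K < n`).
#' @param smoothing Laplace constant s > 0.
#' @param dist_metric distance on the binary features.
#' @return `mlknn_fit()` returns an object of class `mlknn_model` holding
#'   priors and likelihood tables.
#' @examples
#' d <- simulate_cf_dataset(40, m = 12, signature_size = 3, seed = 1)
#' m <- mlknn_fit(d, K = 3)
#' predict(m, simulate_cf_dataset(2, m = 12, signature_size = 3, seed = 2))
#' @export
mlknn_fit <- function(data, K = 1L, smoothing = 1,
                      dist_metric = c("euclidean", "hamming")) {
  stopifnot(inherits(data, "ml_dataset"))
  dist_metric <- match.arg(dist_metric)
  n <- nrow(data)
  if (K >= n) {
    abort("K must be smaller than the number of training cases",
          class = "mlcp_parameter_error")
  }
  s <- smoothing
  alpha <- ml_alphabet(data)
  X <- ml_features(data)
  Y <- vapply(alpha, function(a) {
    vapply(ml_labelsets(data), function(l) a %in% l, logical(1L))
  }, logical(n)) # n x q logical
  D <- cross_dist(X, X, dist_metric)
  # leave-self-out K nearest neighbours, distance ties broken by case index
  nb_counts <- matrix(0L, n, length(alpha), dimnames = list(NULL, alpha))
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])
    nb <- seq_len(n)[-i][ord[seq_len(K)]]
    nb_counts[i, ] <- colSums(Y[nb, , drop = FALSE])
  }
  priors <- (s + colSums(Y)) / (2 * s + n)
  lik1 <- lik0 <- matrix(0, length(alpha), K + 1L,
                         dimnames = list(alpha, as.character(0:K)))
  for (a in alpha) {
    for (j in 0:K) {
      c1 <- sum(Y[, a] & nb_counts[, a] == j)
      c0 <- sum(!Y[, a] & nb_counts[, a] == j)
      lik1[a, j + 1L] <- (s + c1) / (s * (K + 1L) + sum(Y[, a]))
      lik0[a, j + 1L] <- (s + c0) / (s * (K + 1L) + sum(!Y[, a]))
    }
  }
  structure(list(K = as.integer(K), smoothing = s, priors = priors,
                 lik1 = lik1, lik0 = lik0, X = X, Y = Y,
                 alphabet = alpha, dist_metric = dist_metric,
                 feature_cols = attr(data, "feature_cols")),
            class = "mlknn_model")
}

#' @export
print.mlknn_model <- function(x, ...) {
  cat(sprintf("<mlknn_model> K = %d, n = %d, q = %d\n",
              x$K, nrow(x$X), length(x$alphabet)))
  invisible(x)
}

#' @method glance mlknn_model
#' @export
glance.mlknn_model <- function(x, ...) {
  tibble::tibble(method = "ml-knn", K = x$K, smoothing = x$smoothing,
                 n_cases = nrow(x$X), n_labels = length(x$alphabet))
}

#' @method tidy mlknn_model
#' @export
tidy.mlknn_model <- function(x, ...) {
  tibble::tibble(label = x$alphabet, prior = unname(x$priors))
}

#' Posterior label probabilities for new cases
#'
#' @param object an `mlknn_model`.
#' @param newdata an [ml_dataset()], data frame or feature matrix.
#' @param threshold posterior cut-off in (0, 1) defining the region.
#' @param ... ignored.
#' @return A tibble with `case_id`, one posterior column per label,
#'   `threshold` and a `region` list-column.
#' @export
predict.mlknn_model <- function(object, newdata, threshold = 0.5, ...) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = "mlcp_parameter_error")
  }
  X <- as_feature_matrix(newdata, object$feature_cols)
  post <- mlknn_posteriors(object, X)
  out <- tibble::as_tibble(as.data.frame(post, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(case_id = case_ids_of(newdata, nrow(X))), out)
  out$threshold <- threshold
  out$region <- lapply(seq_len(nrow(post)), function(i) {
    object$alphabet[post[i, ] > threshold]
  })
  out
}

mlknn_posteriors <- function(object, X) {
  n <- nrow(object$X)
  K <- object$K
  D <- cross_dist(X, object$X, object$dist_metric)
  post <- matrix(NA_real_, nrow(X), length(object$alphabet),
                 dimnames = list(NULL, object$alphabet))
  for (i in seq_len(nrow(X))) {
    ord <- order(D[i, ], seq_len(n))
    nb <- ord[seq_len(K)]
    cnt <- colSums(object$Y[nb, , drop = FALSE])
    for (a in object$alphabet) {
      j <- cnt[[a]] + 1L
      p1 <- object$priors[[a]] * object$lik1[a, j]
      p0 <- (1 - object$priors[[a]]) * object$lik0[a, j]
      post[i, a] <- p1 / (p1 + p0)
    }
  }
  post
}
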