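#' Fit a conformal predictor on multi-label data
#'
#' Implements the transductive conformal predictor over PT5-expanded
#' single-label examples. The underlying model (random forest, K-nearest
#' neighbours, or Bernoulli naive Bayes) is fitted once on the training
#' rows; each training row's nonconformity score under its own label is
#' precomputed with its origin case excluded from the comparison pools, so
#' that a training row is scored against a bag that never contains its own
#' PT5 replicates — the same situation a test instance faces.
#'
#' @param data an [ml_dataset()] (PT5-transformed internally) or a `pt5_df`.
#' @param method nonconformity scorer: `"rf"` (random-forest proximity
#'   ratio), `"knn"` (distance ratio) or `"nbc"` (naive-Bayes posterior).
#' @param K neighbour count for the rf/knn scorers.
#' @param ntree,mtry random-forest size; `mtry` defaults to
#'   `floor(sqrt(M))`.
#' @param seed integer seed for the forest's bootstrap/feature sampling.
#' @param smoothing Laplace constant for the nbc scorer.
#' @param dist_metric distance for the knn scorer on binary features.
#' @return An object of class `cp_model`.
#' @examples
#' d <- simulate_cf_dataset(30, m = 12, signature_size = 3, seed = 1)
#' m <- cp_fit(d, method = "rf", ntree = 100, seed = 1)
#' cp_predict(m, simulate_cf_dataset(3, m = 12, signature_size = 3, seed = 2),
#'            confidence = 0.9)
#' @export
cp_fit <- function(data, method = c("rf", "knn", "nbc"), K = 1L,
                   ntree = 1000L, mtry = NULL, seed = 1L, smoothing = 1,
                   dist_metric = c("euclidean", "hamming")) {
  method <- match.arg(method)
  dist_metric <- match.arg(dist_metric)
  train <- if (inherits(data, "ml_dataset")) pt5_transform(data) else data
  stopifnot(inherits(train, "pt5_df"))
  X <- ml_features(train)
  labels <- train$label
  origin <- train$origin
  n <- nrow(X)
  if (n < 1L) abort("empty training set", class = "mlcp_empty_input")
  obj <- list(method = method, K = as.integer(K), alphabet = ml_alphabet(train),
              feature_cols = attr(train, "feature_cols"),
              X = X, labels = labels, origin = origin, n = n,
              smoothing = smoothing, dist_metric = dist_metric, seed = seed)
  if (method == "rf") {
    obj$forest <- fit_forest(train, ntree = ntree, mtry = mtry, seed = seed)
    prox <- forest_proximity(obj$forest)$values
    obj$train_alpha <- vapply(seq_len(n), function(j) {
      rf_nonconformity(prox[j, ], labels, labels[j], K = K,
                       exclude = which(origin == origin[j]))
    }, numeric(1L))
  } else if (method == "knn") {
    D <- cross_dist(X, X, dist_metric)
    obj$train_alpha <- vapply(seq_len(n), function(j) {
      knn_nonconformity(D[j, ], labels, labels[j], K = K,
                        exclude = which(origin == origin[j]))
    }, numeric(1L))
  } else {
    nb <- fit_nbc(X, labels, alphabet = obj$alphabet, smoothing = smoothing)
    obj$nbc <- nb
    obj$train_alpha <- vapply(seq_len(n), function(j) {
      rows <- which(origin == origin[j])
      loo <- nbc_drop_rows(nb, X[rows, , drop = FALSE], labels[rows])
      nbc_nonconformity(loo, X[j, ], labels[j])
    }, numeric(1L))
  }
  structure(obj, class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("<cp_model> method cp-%s, %d PT5 examples, q = %d, K = %d\n",
              x$method, x$n, length(x$alphabet), x$K))
  invisible(x)
}

#' @method glance cp_model
#' @export
glance.cp_model <- function(x, ...) {
  tibble::tibble(method = paste0("cp-", x$method), n_examples = x$n,
                 n_labels = length(x$alphabet), K = x$K, seed = x$seed)
}

#' Conformal p-value from nonconformity scores
#'
#' The algorithmic-randomness p-value of a test example with nonconformity
#' `test_alpha` against training scores `train_alpha`:
#' `p = (#\{j : alpha_j >= alpha_test\} + 1) / (n' + 1)` — the `+ 1` counts
#' the test example itself. Un-smoothed (ties counted fully), so results are
#' deterministic; `Inf >= Inf` counts as a tie.
#'
#' @param train_alpha numeric vector of training nonconformity scores.
#' @param test_alpha one or more test scores.
#' @return p-values in `[1/(n'+1), 1]`, one per test score.
#' @examples
#' conformal_pvalue(c(0.1, 0.2, 0.3, 0.4), 0.25) # 3/5
#' @export
conformal_pvalue <- function(train_alpha, test_alpha) {
  n <- length(train_alpha)
  vapply(test_alpha,
         function(a) (sum(train_alpha >= a) + 1) / (n + 1),
         numeric(1L))
}

#' Per-label conformal p-values for test instances
#'
#' For each test instance and each candidate label y, the instance is scored
#' under y with the fitted scorer (the model is *not* refitted per
#' candidate) and its score is ranked among the training scores via
#' [conformal_pvalue()]. Small p means the candidate label does not conform.
#'
#' @param object a [cp_fit()] model.
#' @param newdata an [ml_dataset()], data frame or feature matrix.
#' @return A tibble of class `cp_pvalues`: `case_id` plus one p-value column
#'   per alphabet label.
#' @export
cp_pvalues <- function(object, newdata) {
  stopifnot(inherits(object, "cp_model"))
  X <- as_feature_matrix(newdata, object$feature_cols)
  alpha_test <- cp_test_alphas(object, X)
  p <- apply(alpha_test, c(1L, 2L), function(a) {
    conformal_pvalue(object$train_alpha, a)
  })
  out <- tibble::as_tibble(as.data.frame(p, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(case_id = case_ids_of(newdata, nrow(X))), out)
  structure(out, alphabet = object$alphabet,
            class = c("cp_pvalues", class(tibble::tibble())))
}

# n_test x q matrix of nonconformity scores under each candidate label
cp_test_alphas <- function(object, X) {
  q <- length(object$alphabet)
  out <- matrix(NA_real_, nrow(X), q,
                dimnames = list(NULL, object$alphabet))
  if (object$method == "rf") {
    tp <- forest_proximity(object$forest, X)$test_rows
    for (i in seq_len(nrow(X))) {
      for (y in object$alphabet) {
        out[i, y] <- rf_nonconformity(tp[i, ], object$labels, y, K = object$K)
      }
    }
  } else if (object$method == "knn") {
    D <- cross_dist(X, object$X, object$dist_metric)
    for (i in seq_len(nrow(X))) {
      for (y in object$alphabet) {
        out[i, y] <- knn_nonconformity(D[i, ], object$labels, y, K = object$K)
      }
    }
  } else {
    for (i in seq_len(nrow(X))) {
      post <- nbc_posterior(object$nbc, X[i, ])
      out[i, ] <- 1 - post[object$alphabet]
    }
  }
  out
}

#' Cut p-values into a region prediction
#'
#' At confidence t (significance eps = 1 - t) the region keeps every label
#' whose p-value exceeds eps. Raising the confidence can only grow the
#' region (nesting).
#'
#' @param data a `cp_pvalues` tibble from [cp_pvalues()], or a named numeric
#'   p-value vector.
#' @param confidence threshold t in (0, 1).
#' @return The tibble with `confidence` and a `region` list-column added (or
#'   a character vector of labels for vector input).
#' @examples
#' predict_region(c(a = 0.9, b = 0.3, c = 0.04, d = 0.01), 0.95)
#' @export
predict_region <- function(data, confidence) {
  if (length(confidence) != 1L || confidence <= 0 || confidence >= 1) {
    abort("confidence must be a single number in (0, 1)",
          class = "mlcp_parameter_error")
  }
  eps <- 1 - confidence
  if (is.numeric(data)) {
    return(names(data)[data > eps])
  }
  stopifnot(inherits(data, "cp_pvalues"))
  alpha <- attr(data, "alphabet")
  P <- as.matrix(data[, alpha, drop = FALSE])
  data$confidence <- confidence
  data$region <- lapply(seq_len(nrow(P)), function(i) {
    alpha[P[i, ] > eps]
  })
  data
}

#' Fit-and-cut convenience wrapper
#'
#' @inheritParams cp_pvalues
#' @inheritParams predict_region
#' @return A tibble with case ids, p-value columns, `confidence` and the
#'   `region` list-column.
#' @export
cp_predict <- function(object, newdata, confidence = 0.95) {
  predict_region(cp_pvalues(object, newdata), confidence)
}

#' Online calibration curve of a conformal predictor
#'
#' Processes an exchangeable stream one example at a time: at each step the
#' predictor is fitted on everything seen so far and predicts the next
#' example, and errors are tallied at each significance level. Two error
#' events are reported for case streams: the single-label event (a true
#' label's p-value falls at or below eps; one event per PT5 replicate of the
#' case), whose online error rate is bounded by eps under exchangeability,
#' and the multi-label event (the true label *set* is not contained in the
#' region), for which no theoretical bound is claimed — it is measured.
#' With `unit = "row"` the stream is the shuffled PT5 expansion itself and
#' only the single-label event applies.
#'
#' @param data an [ml_dataset()] stream, in presentation order.
#' @param method,K,ntree,mtry,smoothing,dist_metric scorer configuration,
#'   as in [cp_fit()].
#' @param significance significance levels eps to tally.
#' @param unit `"case"` (predict whole cases) or `"row"` (shuffle the PT5
#'   rows into a single-label stream).
#' @param burn_in examples seen before scoring starts.
#' @param seed seed; step t uses forest seed `seed + t`, and `unit = "row"`
#'   shuffles with `seed`.
#' @return A tibble of class `cp_calibration` with columns `event`,
#'   `significance`, `confidence`, `steps`, `errors`, `error_rate`.
#' @export
online_error_curve <- function(data, method = c("rf", "knn", "nbc"),
                               significance = c(0.01, 0.05, 0.1, 0.2),
                               unit = c("case", "row"), burn_in = 10L,
                               K = 1L, ntree = 100L, mtry = NULL,
                               seed = 1L, smoothing = 1,
                               dist_metric = "euclidean") {
  method <- match.arg(method)
  unit <- match.arg(unit)
  stopifnot(all(significance > 0 & significance < 1))
  if (nrow(data) < 10L) {
    warn("stream has fewer than 10 cases; error rates will be noisy")
  }
  if (unit == "row") {
    rows <- pt5_transform(data)
    perm <- withr::with_seed(as.integer(seed),
                             sample.int(nrow(rows)))
    X <- ml_features(rows)[perm, , drop = FALSE]
    stream <- new_pt5_df(X, rows$label[perm],
                         origin = seq_along(perm),
                         alphabet = ml_alphabet(rows))
    truths <- lapply(stream$label, identity)
    n <- nrow(stream)
  } else {
    stream <- data
    truths <- ml_labelsets(data)
    n <- nrow(data)
  }
  start <- max(2L, burn_in + 1L)
  sl_err <- matrix(0L, 0L, length(significance))
  ml_err <- matrix(0L, 0L, length(significance))
  for (t in start:n) {
    if (unit == "row") {
      train <- new_pt5_df(ml_features(stream)[seq_len(t - 1L), , drop = FALSE],
                          stream$label[seq_len(t - 1L)],
                          origin = seq_len(t - 1L),
                          alphabet = ml_alphabet(stream))
      test_x <- ml_features(stream)[t, , drop = FALSE]
    } else {
      train <- ml_subset(stream, seq_len(t - 1L))
      test_x <- ml_features(stream)[t, , drop = FALSE]
    }
    model <- cp_fit(train, method = method, K = K, ntree = ntree,
                    mtry = mtry, seed = seed + t, smoothing = smoothing,
                    dist_metric = dist_metric)
    pv <- cp_pvalues(model, test_x)
    p <- setNames(unlist(pv[1L, model$alphabet]), model$alphabet)
    true <- truths[[t]]
    sl <- vapply(significance,
                 function(e) sum(p[true] <= e), integer(1L))
    sl_err <- rbind(sl_err, sl)
    ml_err <- rbind(ml_err, as.integer(sl > 0L))
  }
  n_steps <- nrow(sl_err)
  sl_steps <- sum(lengths(truths[start:n]))
  out <- tibble::tibble(
    event = "single_label",
    significance = significance,
    confidence = 1 - significance,
    steps = sl_steps,
    errors = colSums(sl_err),
    error_rate = colSums(sl_err) / sl_steps)
  if (unit == "case") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      event = "multilabel",
      significance = significance,
      confidence = 1 - significance,
      steps = n_steps,
      errors = colSums(ml_err),
      error_rate = colSums(ml_err) / n_steps))
  }
  structure(out, unit = unit, method = method,
            class = c("cp_calibration", class(tibble::tibble())))
}

#' @method tidy cp_calibration
#' @export
tidy.cp_calibration <- function(x, ...) tibble::as_tibble(x)

#' Plot an empirical calibration curve
#'
#' Accuracy (one minus empirical error rate) against confidence level, with
#' the exact-calibration diagonal overlaid: curves on or above the diagonal
#' indicate exact or conservative calibration.
#'
#' @param object a `cp_calibration` tibble from [online_error_curve()] or a
#'   calibration table from [loocv_evaluate()] reports.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot cp_calibration
#' @export
autoplot.cp_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$accuracy <- 1 - df$error_rate
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$accuracy,
                                   colour = .data$event)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "confidence level", y = "accuracy",
                  title = "Empirical calibration",
                  subtitle = "dashed: exact calibration") +
    ggplot2::theme_minimal()
}
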