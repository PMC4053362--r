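#' Leave-one-out evaluation of a multi-label method
#'
#' Runs leave-one-out cross-validation: each case in turn is held out, the
#' model is fitted on the remaining cases (PT5-transformed for the conformal
#' methods), per-label confidence scores are obtained for the held-out case,
#' and regions are cut at every threshold. For conformal methods the
#' threshold is a confidence level (region = labels with p-value above
#' 1 - threshold); for ML-KNN it is a posterior probability cut-off. The six
#' multi-label metrics are computed per threshold, with the four ranking
#' metrics reported both threshold-free ("scores" view) and with region
#' members ranked first ("region" view). The multi-label calibration error
#' rate per threshold is reported alongside.
#'
#' Fold `i` uses forest seed `seed + i`, so results are reproducible and
#' independent of evaluation order.
#'
#' @param data an [ml_dataset()].
#' @param method one of `"cp-rf"`, `"cp-knn"`, `"cp-nbc"`, `"ml-knn"`.
#' @param K neighbour count.
#' @param thresholds vector of thresholds in (0, 1).
#' @param ntree,mtry forest parameters (`"cp-rf"` only); `mtry` defaults to
#'   `floor(sqrt(M))`.
#' @param smoothing Laplace constant for `"cp-nbc"` / `"ml-knn"`.
#' @param dist_metric distance for the knn-based methods.
#' @param seed integer seed.
#' @return An object of class `ml_report`: a list with `predictions`
#'   (tibble: `case_id`, `truth`, `scores`), `metrics` (tibble: `method`,
#'   `K`, `threshold`, `view`, `metric`, `value`), `calibration`
#'   (`cp_calibration` tibble of the multi-label error per threshold) and
#'   `config`.
#' @examples
#' d <- simulate_cf_dataset(25, m = 12, signature_size = 3, seed = 1)
#' r <- loocv_evaluate(d, method = "cp-rf", ntree = 50,
#'                     thresholds = c(0.8, 0.9), seed = 1)
#' tidy(r)
#' @export
loocv_evaluate <- function(data, method = c("cp-rf", "cp-knn", "cp-nbc",
                                            "ml-knn"),
                           K = 1L, thresholds = seq(0.5, 0.99, by = 0.01),
                           ntree = 1000L, mtry = NULL, smoothing = 1,
                           dist_metric = "euclidean", seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "ml_dataset"),
            all(thresholds > 0 & thresholds < 1), length(thresholds) > 0L)
  n <- nrow(data)
  alphabet <- ml_alphabet(data)
  scores <- vector("list", n)
  failures <- character()
  for (i in seq_len(n)) {
    train <- ml_subset(data, setdiff(seq_len(n), i))
    test_x <- ml_features(data)[i, , drop = FALSE]
    res <- tryCatch({
      if (method == "ml-knn") {
        fit <- mlknn_fit(train, K = K, smoothing = smoothing,
                         dist_metric = dist_metric)
        drop(mlknn_posteriors(fit, test_x))
      } else {
        fit <- cp_fit(train, method = sub("^cp-", "", method), K = K,
                      ntree = ntree, mtry = mtry, seed = seed + i,
                      smoothing = smoothing, dist_metric = dist_metric)
        pv <- cp_pvalues(fit, test_x)
        setNames(unlist(pv[1L, alphabet]), alphabet)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("fold %d: %s", i, conditionMessage(res)))
      scores[[i]] <- setNames(rep(NA_real_, length(alphabet)), alphabet)
    } else {
      scores[[i]] <- res
    }
  }
  if (length(failures)) {
    warn(paste0("LOOCV fold failures:\n", paste(failures, collapse = "\n")))
  }
  predictions <- tibble::tibble(case_id = data$case_id,
                                truth = ml_labelsets(data),
                                scores = scores)
  ok <- !vapply(scores, anyNA, logical(1L))
  metrics <- list()
  calib <- list()
  for (t in if (any(ok)) thresholds else numeric()) {
    preds <- predictions[ok, ]
    preds$region <- lapply(preds$scores, function(s) {
      if (method == "ml-knn") names(s)[s > t] else names(s)[s > 1 - t]
    })
    for (view in c("scores", "region")) {
      # the full-alphabet-truth note is emitted once, below, not per cell
      m <- suppressMessages(ml_metrics(preds, alphabet, ranking_view = view))
      m$method <- method
      m$K <- K
      m$threshold <- t
      m$view <- view
      metrics[[length(metrics) + 1L]] <- m
    }
    err <- mapply(mll_calibration_event, preds$region, preds$truth)
    calib[[length(calib) + 1L]] <- tibble::tibble(
      event = "multilabel", significance = 1 - t, confidence = t,
      steps = nrow(preds), errors = sum(err), error_rate = mean(err))
  }
  n_full <- sum(lengths(ml_labelsets(data)) == length(alphabet))
  if (n_full > 0L && any(ok)) {
    message(n_full, " case(s) with a full-alphabet truth skipped in ",
            "ranking loss")
  }
  metrics <- if (length(metrics)) {
    dplyr::bind_rows(metrics)[, c("method", "K", "threshold",
                                  "view", "metric", "value")]
  } else {
    tibble::tibble(method = character(), K = integer(),
                   threshold = numeric(), view = character(),
                   metric = character(), value = numeric())
  }
  calibration <- structure(dplyr::bind_rows(calib),
                           unit = "case", method = method,
                           class = c("cp_calibration",
                                     class(tibble::tibble())))
  structure(list(predictions = predictions, metrics = metrics,
                 calibration = calibration, failures = failures,
                 config = list(method = method, K = K, ntree = ntree,
                               mtry = mtry, thresholds = thresholds,
                               smoothing = smoothing,
                               dist_metric = dist_metric, seed = seed,
                               n = n, alphabet = alphabet)),
            class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat(sprintf("<ml_report> %s (K = %d) on %d cases, %d thresholds\n",
              x$config$method, x$config$K, x$config$n,
              length(x$config$thresholds)))
  print(glance(x))
  invisible(x)
}

#' @method tidy ml_report
#' @export
tidy.ml_report <- function(x, ...) x$metrics

#' @method glance ml_report
#' @export
glance.ml_report <- function(x, ...) {
  t_max <- max(x$config$thresholds)
  m <- x$metrics[x$metrics$threshold == t_max & x$metrics$view == "scores", ]
  out <- tibble::as_tibble(setNames(as.list(m$value), m$metric))
  dplyr::bind_cols(tibble::tibble(method = x$config$method,
                                  K = x$config$K, threshold = t_max), out)
}

#' Tidy per-threshold metric table from one or more reports
#'
#' @param ... [loocv_evaluate()] reports (or a single list of them).
#' @param view ranking view to keep (see [ml_metrics()]).
#' @return A tibble with columns `method`, `K`, `threshold`, `metric`,
#'   `value`.
#' @export
threshold_sweep <- function(..., view = "scores") {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "ml_report")) {
    reports <- reports[[1L]]
  }
  out <- dplyr::bind_rows(lapply(reports, function(r) r$metrics))
  out[out$view == view, setdiff(names(out), "view")]
}

#' Plot metric curves across thresholds
#'
#' @param object an `ml_report`.
#' @param metrics which metrics to facet; default all six.
#' @param view ranking view (see [ml_metrics()]).
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot ml_report
#' @export
autoplot.ml_report <- function(object, metrics = NULL, view = "scores", ...) {
  df <- object$metrics[object$metrics$view == view, ]
  if (!is.null(metrics)) df <- df[df$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "threshold (confidence level / posterior cut-off)",
                  y = NULL,
                  title = sprintf("%s (K = %d), leave-one-out",
                                  object$config$method, object$config$K)) +
    ggplot2::theme_minimal()
}
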