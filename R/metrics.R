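#' Rank labels by confidence score
#'
#' Descending-score ranks (1 = most confident). Ties are broken by alphabet
#' order, the fixed ordering carried by the dataset, so rankings are
#' deterministic.
#'
#' @param scores named numeric vector of per-label confidence scores
#'   (conformal p-values or posteriors), named by and covering the alphabet.
#' @param alphabet ordered label alphabet; defaults to `names(scores)`.
#' @return Integer ranks named by label.
#' @examples
#' rank_labels(c(a = 0.9, b = 0.3, c = 0.04, d = 0.01))
#' @export
rank_labels <- function(scores, alphabet = names(scores)) {
  stopifnot(all(alphabet %in% names(scores)))
  s <- scores[alphabet]
  ord <- order(-s, seq_along(s))
  ranks <- integer(length(s))
  ranks[ord] <- seq_along(s)
  setNames(ranks, alphabet)
}

# region-restricted ranking: labels inside the region come first (by score,
# ties by alphabet), labels outside follow in alphabet order
rank_labels_region <- function(scores, region, alphabet = names(scores)) {
  s <- scores[alphabet]
  inside <- alphabet %in% region
  ord <- order(-inside, -s * inside, seq_along(s))
  ranks <- integer(length(s))
  ranks[ord] <- seq_along(s)
  setNames(ranks, alphabet)
}

#' Multi-label evaluation metrics
#'
#' The six standard multi-label metrics over a batch of scored predictions.
#' `predictions` is a tibble with list-columns `truth` (true label sets,
#' non-empty), `region` (predicted label sets) and `scores` (named numeric
#' confidence vectors over the full alphabet).
#'
#' * subset accuracy — fraction of cases whose region equals the truth
#'   exactly (higher is better);
#' * hamming loss — mean symmetric difference between region and truth,
#'   divided by the alphabet size q;
#' * one-error — fraction of cases whose top-ranked label is not in the
#'   truth;
#' * coverage — mean over cases of (worst rank among true labels) - 1: how
#'   far down the ranking one must go to cover all true labels;
#' * ranking loss — fraction of (true, false) label pairs ranked in the
#'   wrong order, averaged over cases with both pools non-empty (cases whose
#'   truth is the full alphabet are skipped, with a message);
#' * average precision — for each true label, the fraction of labels ranked
#'   at or above it that are true, averaged over true labels then cases.
#'
#' @param predictions tibble with list-columns `truth`, `region`, `scores`.
#' @param alphabet ordered label alphabet (default: names of the first
#'   score vector).
#' @param ranking_view `"scores"` ranks by raw confidence scores
#'   (threshold-free); `"region"` ranks region members first and the rest in
#'   alphabet order, so ranking metrics respond to the threshold.
#' @return `ml_metrics()` a tibble `metric`/`value`; the individual metric
#'   functions return a single number.
#' @examples
#' preds <- tibble::tibble(
#'   truth = list(c("a", "b"), "a"),
#'   region = list(c("a", "b"), c("a", "c")),
#'   scores = list(c(a = .9, b = .8, c = .1, d = 0),
#'                 c(a = .9, b = .1, c = .6, d = 0)))
#' ml_metrics(preds, alphabet = letters[1:4])
#' @export
ml_metrics <- function(predictions, alphabet = NULL,
                       ranking_view = c("scores", "region")) {
  ranking_view <- match.arg(ranking_view)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  tibble::tibble(
    metric = c("subset_accuracy", "hamming_loss", "one_error", "coverage",
               "ranking_loss", "average_precision"),
    value = c(subset_accuracy(predictions),
              hamming_loss(predictions, alphabet),
              one_error(predictions, alphabet, ranking_view),
              coverage(predictions, alphabet, ranking_view),
              ranking_loss(predictions, alphabet, ranking_view),
              average_precision(predictions, alphabet, ranking_view)))
}

check_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("truth", "region") %in% names(predictions)),
            nrow(predictions) > 0L)
  if (any(lengths(predictions$truth) == 0L)) {
    abort("every true label set must be non-empty")
  }
  invisible(predictions)
}

#' @rdname ml_metrics
#' @export
subset_accuracy <- function(predictions) {
  check_predictions(predictions)
  mean(mapply(function(r, t) setequal(r, t),
              predictions$region, predictions$truth))
}

#' @rdname ml_metrics
#' @export
hamming_loss <- function(predictions, alphabet = NULL) {
  check_predictions(predictions)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  q <- length(alphabet)
  mean(mapply(function(r, t) {
    length(union(setdiff(r, t), setdiff(t, r))) / q
  }, predictions$region, predictions$truth))
}

case_ranks <- function(predictions, alphabet, ranking_view) {
  if (ranking_view == "scores") {
    lapply(predictions$scores, rank_labels, alphabet = alphabet)
  } else {
    mapply(rank_labels_region, predictions$scores, predictions$region,
           MoreArgs = list(alphabet = alphabet), SIMPLIFY = FALSE)
  }
}

#' @rdname ml_metrics
#' @export
one_error <- function(predictions, alphabet = NULL,
                      ranking_view = c("scores", "region")) {
  ranking_view <- match.arg(ranking_view)
  check_predictions(predictions)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  ranks <- case_ranks(predictions, alphabet, ranking_view)
  mean(mapply(function(rk, t) !(names(rk)[rk == 1L] %in% t),
              ranks, predictions$truth))
}

#' @rdname ml_metrics
#' @export
coverage <- function(predictions, alphabet = NULL,
                     ranking_view = c("scores", "region")) {
  ranking_view <- match.arg(ranking_view)
  check_predictions(predictions)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  ranks <- case_ranks(predictions, alphabet, ranking_view)
  mean(mapply(function(rk, t) max(rk[t]) - 1L, ranks, predictions$truth))
}

#' @rdname ml_metrics
#' @export
ranking_loss <- function(predictions, alphabet = NULL,
                         ranking_view = c("scores", "region")) {
  ranking_view <- match.arg(ranking_view)
  check_predictions(predictions)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  ranks <- case_ranks(predictions, alphabet, ranking_view)
  per_case <- mapply(function(rk, t) {
    false <- setdiff(alphabet, t)
    if (length(false) == 0L) return(NA_real_)
    bad <- 0L
    for (y in t) for (z in false) if (rk[z] < rk[y]) bad <- bad + 1L
    bad / (length(t) * length(false))
  }, ranks, predictions$truth)
  if (anyNA(per_case)) {
    message(sum(is.na(per_case)),
            " case(s) with a full-alphabet truth skipped in ranking loss")
  }
  mean(per_case, na.rm = TRUE)
}

#' @rdname ml_metrics
#' @export
average_precision <- function(predictions, alphabet = NULL,
                              ranking_view = c("scores", "region")) {
  ranking_view <- match.arg(ranking_view)
  check_predictions(predictions)
  if (is.null(alphabet)) alphabet <- names(predictions$scores[[1L]])
  ranks <- case_ranks(predictions, alphabet, ranking_view)
  mean(mapply(function(rk, t) {
    mean(vapply(t, function(y) {
      sum(rk[t] <= rk[y]) / rk[y]
    }, numeric(1L)))
  }, ranks, predictions$truth))
}

#' Multi-label calibration error event
#'
#' `TRUE` when the true label set is *not* contained in the prediction
#' region — the multi-label analogue of a conformal error, whose empirical
#' rate is compared against the significance level in calibration
#' diagnostics.
#'
#' @param region predicted label set.
#' @param truth true label set.
#' @return Logical scalar.
#' @examples
#' mll_calibration_event(c("a", "b"), "a")         # FALSE: subset covered
#' mll_calibration_event("a", c("a", "b"))          # TRUE: b missed
#' @export
mll_calibration_event <- function(region, truth) {
  !all(truth %in% region)
}
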