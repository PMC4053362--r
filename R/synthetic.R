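#' Simulate chronic-fatigue-like multi-label symptom data
#'
#' Generates binary symptom matrices with known multi-label structure,
#' emulating the shape of clinical syndrome-differentiation data: q syndrome
#' factors (default 4), M binary symptoms (default 95), and per-case label
#' sets of size 1..q with controllable marginal prevalence and pairwise
#' co-occurrence. Each label owns `signature_size` dedicated features,
#' disjoint across labels, that fire with probability `signal` when the
#' label is present; every feature also fires spontaneously with probability
#' `background`. With `signal = 1, background = 0` the label set is exactly
#' recoverable from the firing signatures, which gives a noiseless regime
#' for sanity checks.
#'
#' Label sets are drawn from an exact log-linear model over the 2^q - 1
#' non-empty subsets: the log-weight of a set S is
#' sum over l in S of logit-prevalence(l) + sum over pairs {l, m} in S of
#' `cooccurrence[l, m]`. With `cooccurrence = 0` the labels are independent
#' Bernoulli draws conditioned on non-emptiness, so empirical marginals track
#' `label_prevalence` up to that conditioning.
#'
#' @param n number of cases.
#' @param m number of binary features.
#' @param alphabet ordered label names; the default mirrors the four
#'   syndrome factors commonly used for chronic fatigue.
#' @param label_prevalence per-label marginal probability before the
#'   non-emptiness conditioning (recycled to length q).
#' @param cooccurrence q x q symmetric matrix of pairwise log-linear
#'   dependence weights (0 = independence), or a single number applied to
#'   every pair.
#' @param signature_size informative features dedicated to each label;
#'   `q * signature_size` must not exceed `m`.
#' @param signal probability a signature feature fires given its label is
#'   present; must exceed `background` for a separable regime.
#' @param background probability any feature fires spontaneously.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return An [ml_dataset()] with `n` rows and `m` feature columns.
#' @examples
#' d <- simulate_cf_dataset(20, m = 12, signature_size = 3, seed = 1)
#' table(lengths(ml_labelsets(d)))
#' @export
simulate_cf_dataset <- function(n, m = 95,
                                alphabet = cf_syndrome_factors(),
                                label_prevalence = c(0.55, 0.35, 0.40, 0.50),
                                cooccurrence = 0,
                                signature_size = 6,
                                signal = 0.9, background = 0.05,
                                seed = 1L) {
  q <- length(alphabet)
  validate_alphabet(alphabet)
  label_prevalence <- rep_len(label_prevalence, q)
  if (any(label_prevalence <= 0 | label_prevalence >= 1)) {
    abort("label_prevalence must lie strictly inside (0, 1)",
          class = "mlcp_config_error")
  }
  if (any(c(signal, background) < 0 | c(signal, background) > 1)) {
    abort("signal and background must be probabilities",
          class = "mlcp_config_error")
  }
  if (q * signature_size > m) {
    abort("infeasible config: q * signature_size exceeds the feature count",
          class = "mlcp_config_error")
  }
  if (length(cooccurrence) == 1L) {
    cooccurrence <- matrix(cooccurrence, q, q)
    diag(cooccurrence) <- 0
  }
  stopifnot(identical(dim(cooccurrence), c(q, q)))

  withr::with_seed(as.integer(seed), {
    sets <- sample_labelsets(n, label_prevalence, cooccurrence)
    X <- matrix(rbinom(n * m, 1L, background), n, m)
    for (l in seq_len(q)) {
      cols <- ((l - 1L) * signature_size + 1L):(l * signature_size)
      has <- vapply(sets, function(s) l %in% s, logical(1L))
      if (any(has) && signature_size > 0L) {
        fired <- matrix(rbinom(sum(has) * signature_size, 1L, signal),
                        sum(has), signature_size)
        X[has, cols] <- pmax(X[has, cols, drop = FALSE], fired)
      }
    }
    colnames(X) <- paste0("s", seq_len(m))
    ml_dataset(X, lapply(sets, function(s) alphabet[s]), alphabet = alphabet)
  })
}

#' @rdname simulate_cf_dataset
#' @export
cf_syndrome_factors <- function() {
  c("spleen deficiency", "heart deficiency", "liver depression",
    "qi deficiency")
}

# exact sampler over the 2^q - 1 non-empty label subsets under a pairwise
# log-linear model; q is small so full enumeration is cheap. Main-effect
# logits are calibrated so the marginal of each label *given non-emptiness*
# equals the requested prevalence (plain conditioning would inflate it).
sample_labelsets <- function(n, prevalence, cooccurrence) {
  q <- length(prevalence)
  if (sum(prevalence) <= 1) {
    abort(paste("sum(label_prevalence) must exceed 1: every case carries at",
                "least one label, so marginals must average >= 1/q"),
          class = "mlcp_config_error")
  }
  subsets <- as.matrix(expand.grid(rep(list(c(0L, 1L)), q)))[-1L, , drop = FALSE]
  logit <- log(prevalence / (1 - prevalence))
  pair <- 0.5 * rowSums((subsets %*% cooccurrence) * subsets)
  for (it in seq_len(500L)) {
    logw <- drop(subsets %*% logit) + pair
    w <- exp(logw - max(logw))
    p <- w / sum(w)
    marg <- drop(crossprod(subsets, p))
    if (max(abs(marg - prevalence)) < 1e-12) break
    logit <- logit + log(prevalence) - log(marg)
  }
  if (max(abs(marg - prevalence)) > 1e-6) {
    abort("label-set sampler failed to calibrate the requested prevalences",
          class = "mlcp_config_error")
  }
  idx <- sample.int(nrow(subsets), n, replace = TRUE, prob = p)
  lapply(idx, function(i) which(subsets[i, ] == 1L))
}
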