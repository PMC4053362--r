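test_that("the p-value counts ties and the test example itself", {
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3, 0.4), 0.25), 3 / 5)
  # extreme nonconformity gives the minimum 1/(n'+1)
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3, 0.4), 9), 1 / 5)
  # full conformity gives 1
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3, 0.4), 0.05), 1)
  # Inf sentinels compare as maximal, Inf >= Inf is a tie
  expect_equal(conformal_pvalue(c(0.5, Inf, Inf), Inf), 3 / 4)
  set.seed(4)
  for (i in 1:20) {
    ta <- runif(15)
    a <- runif(1)
    expect_equal(conformal_pvalue(ta, a), oracle_pvalue(ta, a))
  }
})

test_that("p-values agree with a naive brute-force conformal pipeline", {
  # end-to-end oracle: naive proximities from the stored leaf assignments,
  # naive pool sums, naive counting p-value
  for (seed in 1:3) {
    d <- random_toy_dataset(10, 6, c("A", "B", "C"), 200 + seed)
    model <- cp_fit(d, method = "rf", K = 2, ntree = 11, seed = seed)
    expect_lte(model$n, 30)
    x <- matrix(sample(0:1, 6, replace = TRUE), 1, 6)
    pv <- cp_pvalues(model, x)

    P_or <- oracle_proximity(model$forest$nodes)
    alpha_or <- vapply(seq_len(model$n), function(j) {
      oracle_rf_alpha(P_or[j, ], model$labels, model$labels[j], K = 2,
                      exclude = which(model$origin == model$origin[j]))
    }, numeric(1))
    nd <- as.data.frame(x)
    colnames(nd) <- model$feature_cols
    tn <- predict(model$forest$forest, nd, type = "terminalNodes",
                  num.threads = 1)$predictions
    tprox <- vapply(seq_len(model$n), function(j) {
      mean(model$forest$nodes[j, ] == tn[1, ])
    }, numeric(1))
    for (y in ml_alphabet(d)) {
      a_test <- oracle_rf_alpha(tprox, model$labels, y, K = 2)
      expect_equal(pv[[y]], oracle_pvalue(alpha_or, a_test))
    }
  }
})

test_that("knn and nbc conformal pipelines also match the naive oracle", {
  d <- random_toy_dataset(9, 5, c("A", "B"), 301)
  x <- matrix(sample(0:1, 5, replace = TRUE), 1, 5)

  m_knn <- cp_fit(d, method = "knn", K = 1)
  pv <- cp_pvalues(m_knn, x)
  X <- m_knn$X
  alpha_or <- vapply(seq_len(m_knn$n), function(j) {
    dj <- sqrt(colSums((t(X) - X[j, ])^2))
    oracle_knn_alpha(dj, m_knn$labels, m_knn$labels[j], K = 1,
                     exclude = which(m_knn$origin == m_knn$origin[j]))
  }, numeric(1))
  dx <- sqrt(colSums((t(X) - drop(x))^2))
  for (y in c("A", "B")) {
    a_test <- oracle_knn_alpha(dx, m_knn$labels, y, K = 1)
    expect_equal(pv[[y]], oracle_pvalue(alpha_or, a_test))
  }

  m_nbc <- cp_fit(d, method = "nbc")
  pv <- cp_pvalues(m_nbc, x)
  full <- fit_nbc(X, m_nbc$labels, alphabet = ml_alphabet(d))
  alpha_or <- vapply(seq_len(m_nbc$n), function(j) {
    rows <- which(m_nbc$origin == m_nbc$origin[j])
    loo <- nbc_drop_rows(full, X[rows, , drop = FALSE], m_nbc$labels[rows])
    1 - nbc_posterior(loo, X[j, ])[[m_nbc$labels[j]]]
  }, numeric(1))
  for (y in c("A", "B")) {
    a_test <- 1 - nbc_posterior(full, drop(x))[[y]]
    expect_equal(pv[[y]], oracle_pvalue(alpha_or, a_test))
  }
})

test_that("p-values live in [1/(n'+1), 1]", {
  d <- random_toy_dataset(12, 6, c("A", "B", "C"), 77)
  model <- cp_fit(d, method = "rf", ntree = 20, seed = 1)
  test <- random_toy_dataset(6, 6, c("A", "B", "C"), 78)
  pv <- cp_pvalues(model, test)
  P <- as.matrix(pv[, ml_alphabet(d)])
  expect_true(all(P >= 1 / (model$n + 1)))
  expect_true(all(P <= 1))
})

test_that("regions are exactly the labels with p above the significance level", {
  p <- c(a = 0.9, b = 0.3, c = 0.04, d = 0.01)
  expect_equal(predict_region(p, 0.95), c("a", "b"))
  expect_equal(predict_region(p, 0.6), "a")
  # confidence close to 1 keeps every label (p >= 1/(n'+1) > eps)
  expect_equal(predict_region(p, 1 - 1e-6), c("a", "b", "c", "d"))
  expect_error(predict_region(p, 1.2), class = "mlcp_parameter_error")
  expect_error(predict_region(p, 0), class = "mlcp_parameter_error")
})

test_that("regions nest as confidence grows", {
  d <- random_toy_dataset(15, 8, c("A", "B", "C", "D"), 9)
  model <- cp_fit(d, method = "rf", ntree = 30, seed = 2)
  test <- random_toy_dataset(5, 8, c("A", "B", "C", "D"), 10)
  pv <- cp_pvalues(model, test)
  grid <- c(0.5, 0.7, 0.9, 0.99)
  for (i in seq_len(nrow(pv))) {
    p <- setNames(unlist(pv[i, ml_alphabet(d)]), ml_alphabet(d))
    regions <- lapply(grid, function(t) predict_region(p, t))
    for (k in seq_along(grid)[-1]) {
      expect_true(all(regions[[k - 1]] %in% regions[[k]]))
    }
  }
})

test_that("a duplicate of the test case in training raises its own-label p-value", {
  d <- random_toy_dataset(14, 6, c("A", "B"), 500)
  sets <- ml_labelsets(d)
  sets[[1]] <- sets[[1]][1] # single-label duplicate
  d <- ml_dataset(ml_features(d), sets, alphabet = ml_alphabet(d))
  x <- ml_features(d)[1, , drop = FALSE]
  truth <- sets[[1]]
  base <- cp_fit(ml_subset(d, 2:14), method = "knn", K = 1)
  p0 <- cp_pvalues(base, x)[[truth]]
  aug <- cp_fit(d, method = "knn", K = 1) # case 1 duplicates the test point
  p1 <- cp_pvalues(aug, x)[[truth]]
  expect_gte(p1, p0)
})

test_that("online error curve is bounded at eps = 0 and warns on short streams", {
  d <- simulate_cf_dataset(8, m = 12, signature_size = 3, seed = 21)
  expect_warning(
    curve <- online_error_curve(d, method = "nbc", significance = 1e-9,
                                burn_in = 2),
    "fewer than 10")
  # eps ~ 0: the region is always the full alphabet, so no errors
  expect_equal(curve$errors, rep(0L, nrow(curve)))
})

test_that("presentation order does not change error rates beyond noise", {
  d <- simulate_cf_dataset(60, m = 16, signature_size = 4, seed = 31)
  shuffled <- ml_subset(d, withr::with_seed(1, sample.int(nrow(d))))
  c1 <- online_error_curve(d, method = "nbc", significance = 0.2,
                           burn_in = 10)
  c2 <- online_error_curve(shuffled, method = "nbc", significance = 0.2,
                           burn_in = 10)
  r1 <- c1$error_rate[c1$event == "single_label"]
  r2 <- c2$error_rate[c2$event == "single_label"]
  n_steps <- c1$steps[c1$event == "single_label"]
  # both are Monte-Carlo estimates of the same bounded quantity
  expect_lt(abs(r1 - r2), 4 * sqrt(0.2 * 0.8 / n_steps) + 0.05)
})
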