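test_that("forest fitting is deterministic and uses floor(sqrt(M)) by default", {
  d <- simulate_cf_dataset(20, m = 95, signature_size = 6, seed = 2)
  tr <- pt5_transform(d)
  f1 <- fit_forest(tr, ntree = 25, seed = 4)
  f2 <- fit_forest(tr, ntree = 25, seed = 4)
  expect_identical(f1$nodes, f2$nodes)
  expect_equal(f1$mtry, 9) # floor(sqrt(95))
  expect_error(fit_forest(tr, ntree = 10, mtry = 1000, seed = 1), "mtry")
})

test_that("degenerate training sets are rejected", {
  one_row <- ml_dataset(matrix(c(1, 0), 1, 2), list("A"),
                        alphabet = c("A", "B"))
  expect_error(fit_forest(pt5_transform(one_row), ntree = 5, seed = 1),
               class = "mlcp_fit_error")
  const <- ml_dataset(matrix(1, 4, 2), as.list(rep("A", 4)),
                      alphabet = c("A", "B"))
  expect_error(fit_forest(pt5_transform(const), ntree = 5, seed = 1),
               class = "mlcp_fit_error")
})

test_that("separable clusters give zero out-of-bag error", {
  X <- rbind(matrix(rep(c(1, 1, 0, 0), 10), 10, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 10), 10, 4, byrow = TRUE))
  d <- ml_dataset(X, as.list(rep(c("A", "B"), each = 10)),
                  alphabet = c("A", "B"))
  f <- fit_forest(pt5_transform(d), ntree = 100, seed = 1)
  expect_equal(unname(f$forest$prediction.error), 0)
})

test_that("proximities match brute-force co-leaf counting and are well formed", {
  for (seed in 1:3) {
    d <- random_toy_dataset(8, 5, c("A", "B", "C"), seed + 100)
    f <- fit_forest(pt5_transform(d), ntree = 5, seed = seed)
    P <- forest_proximity(f)$values
    expect_equal(P, oracle_proximity(f$nodes))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(diag(P)), rep(1, nrow(P)))
    expect_equal(P, t(P))
  }
})

test_that("identical feature vectors have proximity one", {
  d <- ml_dataset(rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(0, 1, 1)),
                  list("A", "B", "B", "A"), alphabet = c("A", "B"))
  f <- fit_forest(pt5_transform(d), ntree = 30, seed = 2)
  P <- forest_proximity(f)$values
  expect_equal(P[1, 2], 1) # rows 1 and 2 share every decision path
})

test_that("test-instance proximities equal per-tree co-leaf fractions", {
  d <- random_toy_dataset(10, 6, c("A", "B"), 55)
  f <- fit_forest(pt5_transform(d), ntree = 7, seed = 3)
  x <- matrix(c(1, 0, 1, 0, 1, 0), 1, 6)
  tp <- forest_proximity(f, x)$test_rows
  nd <- as.data.frame(x)
  colnames(nd) <- f$feature_cols
  tn <- predict(f$forest, nd, type = "terminalNodes",
                num.threads = 1)$predictions
  manual <- vapply(seq_len(nrow(f$nodes)), function(j) {
    mean(f$nodes[j, ] == tn[1, ])
  }, numeric(1))
  expect_equal(drop(tp), manual)
})

test_that("the proximity-ratio score matches a hand oracle on a 6-row toy", {
  labels <- c("A", "A", "A", "B", "B", "B")
  P <- rbind(c(1.0, 0.8, 0.6, 0.3, 0.2, 0.1),
             c(0.8, 1.0, 0.5, 0.4, 0.1, 0.2),
             c(0.6, 0.5, 1.0, 0.2, 0.3, 0.4),
             c(0.3, 0.4, 0.2, 1.0, 0.7, 0.6),
             c(0.2, 0.1, 0.3, 0.7, 1.0, 0.5),
             c(0.1, 0.2, 0.4, 0.6, 0.5, 1.0))
  # evaluating row 1 as "A", K = 2, excluding row 1 itself:
  # two largest B proximities 0.3 + 0.2; two largest A proximities 0.8 + 0.6
  a <- rf_nonconformity(P[1, ], labels, "A", K = 2, exclude = 1)
  expect_equal(a, (0.3 + 0.2) / (0.8 + 0.6))
  expect_equal(a, oracle_rf_alpha(P[1, ], labels, "A", 2, exclude = 1))
  # random spot-checks against the brute-force oracle
  set.seed(1)
  for (i in 1:20) {
    v <- runif(6)
    K <- sample(1:4, 1)
    lab <- sample(c("A", "B"), 1)
    expect_equal(rf_nonconformity(v, labels, lab, K = K),
                 oracle_rf_alpha(v, labels, lab, K))
  }
})

test_that("perfectly conforming and symmetric cases hit the boundary values", {
  labels <- c("A", "A", "B", "B")
  expect_equal(rf_nonconformity(c(1, 1, 0, 0), labels, "A", K = 2), 0)
  expect_equal(rf_nonconformity(c(.5, .5, .5, .5), labels, "A", K = 2), 1)
  # empty pools
  expect_equal(rf_nonconformity(c(.5, .5), c("B", "B"), "A", K = 1), Inf)
  expect_equal(rf_nonconformity(c(.5, .5), c("A", "A"), "A", K = 1), 0)
})

test_that("the proximity-ratio score is scale free", {
  labels <- c("A", "B", "A", "B", "A")
  set.seed(2)
  v <- runif(5)
  for (c_ in c(0.1, 2, 17)) {
    expect_equal(rf_nonconformity(c_ * v, labels, "A", K = 2),
                 rf_nonconformity(v, labels, "A", K = 2))
  }
})

test_that("same-origin PT5 replicates are excluded from both pools", {
  # origin case carries labels A and B: its replicate has proximity 1 and
  # would dominate the different-label pool if not excluded
  labels <- c("A", "B", "A", "B")
  origin <- c(1, 1, 2, 3)
  prox <- c(1, 1, 0.6, 0.4)
  a <- rf_nonconformity(prox, labels, "A", K = 1,
                        exclude = which(origin == 1))
  expect_equal(a, 0.4 / 0.6)
})

test_that("knn distance-ratio score matches hand computation", {
  # 5 points on 2 binary-ish features, K = 1
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(1, 1))
  labels <- c("A", "A", "B", "B", "B")
  d_test <- sqrt(rowSums(sweep(X, 2, c(0, 0))^2)) # distances from (0,0)
  a <- knn_nonconformity(d_test, labels, "A", K = 1)
  expect_equal(a, 0 / 1) # nearest A at 0, nearest B at 1
  expect_equal(knn_nonconformity(rep(2, 5), labels, "A", K = 1), 1)
  set.seed(3)
  for (i in 1:20) {
    v <- runif(5)
    K <- sample(1:3, 1)
    lab <- sample(c("A", "B"), 1)
    expect_equal(knn_nonconformity(v, labels, lab, K = K),
                 oracle_knn_alpha(v, labels, lab, K))
  }
})

test_that("ties among equal proximities resolve by ascending row index", {
  labels <- c("A", "A", "A", "B")
  # rows 1 and 2 tie at 0.5; K = 1 must take row 1's value (same either way)
  # but with K = 2 and values (0.5, 0.5, 0.2) the sum picks both tied rows
  expect_equal(rf_nonconformity(c(.5, .5, .2, .3), labels, "A", K = 2),
               0.3 / (0.5 + 0.5))
})

test_that("naive-Bayes nonconformity matches a hand Bayes-rule oracle", {
  # 4 rows, 2 features, labels A,A,B,B; smoothing 1
  X <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  labels <- c("A", "A", "B", "B")
  nb <- fit_nbc(X, labels, alphabet = c("A", "B"), smoothing = 1)
  # priors: (2+1)/(4+2) = 1/2 each
  # P(f1=1|A) = (2+1)/(2+2) = 3/4 ; P(f2=1|A) = (1+1)/4 = 1/2
  # P(f1=1|B) = (0+1)/4 = 1/4 ; P(f2=1|B) = (1+1)/4 = 1/2
  x <- c(1, 0)
  lA <- 0.5 * (3 / 4) * (1 / 2)
  lB <- 0.5 * (1 / 4) * (1 / 2)
  expect_equal(nbc_nonconformity(nb, x, "A"), 1 - lA / (lA + lB))
  post <- nbc_posterior(nb, x)
  expect_equal(sum(post), 1)
})

test_that("nbc boundary values behave as documented", {
  X <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  nb <- fit_nbc(X, c("A", "A", "B", "B"), alphabet = c("A", "B", "C", "D"))
  post <- nbc_posterior(nb, c(1, 0))
  # a uniform posterior over q = 4 labels gives alpha = 0.75
  nb_sym <- fit_nbc(matrix(0.0, 0, 2), character(),
                    alphabet = c("A", "B", "C", "D"))
  expect_equal(unname(nbc_posterior(nb_sym, c(1, 0))),
               rep(0.25, 4))
  expect_equal(nbc_nonconformity(nb_sym, c(1, 0), "A"), 0.75)
  # labels never seen in training keep posterior > 0 via smoothing
  expect_true(all(post > 0) && all(post < 1))
})

test_that("relabeling an example away from its neighbourhood never lowers alpha", {
  labels <- c("A", "A", "A", "B", "B")
  prox <- c(0.9, 0.8, 0.7, 0.1, 0.05) # clearly an A neighbourhood
  expect_lte(rf_nonconformity(prox, labels, "A", K = 2),
             rf_nonconformity(prox, labels, "B", K = 2))
  d <- c(0.1, 0.2, 0.3, 2, 3)
  expect_lte(knn_nonconformity(d, labels, "A", K = 2),
             knn_nonconformity(d, labels, "B", K = 2))
})
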