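# Independent brute-force oracles: naive loops only, no sorting tricks,
# no shared code with the package internals.

oracle_proximity <- function(nodes) {
  n <- nrow(nodes)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      hits <- 0
      for (t in seq_len(ncol(nodes))) {
        if (nodes[i, t] == nodes[j, t]) hits <- hits + 1
      }
      P[i, j] <- hits / ncol(nodes)
    }
  }
  P
}

# top-K two-pool ratio, proximity orientation (diff pool / same pool)
oracle_rf_alpha <- function(prox, labels, label, K, exclude = integer()) {
  keep <- setdiff(seq_along(prox), exclude)
  same <- sort(prox[keep[labels[keep] == label]], decreasing = TRUE)
  diff <- sort(prox[keep[labels[keep] != label]], decreasing = TRUE)
  if (length(same) == 0) return(Inf)
  if (length(diff) == 0) return(0)
  num <- sum(diff[seq_len(min(K, length(diff)))])
  den <- sum(same[seq_len(min(K, length(same)))])
  if (den == 0) { if (num == 0) 1 else Inf } else num / den
}

oracle_knn_alpha <- function(d, labels, label, K, exclude = integer()) {
  keep <- setdiff(seq_along(d), exclude)
  same <- sort(d[keep[labels[keep] == label]])
  diff <- sort(d[keep[labels[keep] != label]])
  if (length(same) == 0) return(Inf)
  if (length(diff) == 0) return(0)
  num <- sum(same[seq_len(min(K, length(same)))])
  den <- sum(diff[seq_len(min(K, length(diff)))])
  if (den == 0) { if (num == 0) 1 else Inf } else num / den
}

oracle_pvalue <- function(train_alpha, test_alpha) {
  count <- 1 # the test example itself
  for (a in train_alpha) if (a >= test_alpha) count <- count + 1
  count / (length(train_alpha) + 1)
}

# ranking by descending score, ties by position (alphabet) order
oracle_ranks <- function(scores) {
  q <- length(scores)
  ranks <- integer(q)
  taken <- rep(FALSE, q)
  for (r in seq_len(q)) {
    best <- NA
    for (j in seq_len(q)) {
      if (!taken[j] && (is.na(best) || scores[j] > scores[best])) best <- j
    }
    ranks[best] <- r
    taken[best] <- TRUE
  }
  names(ranks) <- names(scores)
  ranks
}

oracle_metrics <- function(truths, regions, score_list, alphabet) {
  n <- length(truths)
  q <- length(alphabet)
  sa <- hl <- oe <- cov <- ap <- 0
  rl <- c()
  for (i in seq_len(n)) {
    t <- truths[[i]]; r <- regions[[i]]
    sa <- sa + as.numeric(setequal(t, r))
    hl <- hl + length(union(setdiff(t, r), setdiff(r, t))) / q
    rk <- oracle_ranks(score_list[[i]][alphabet])
    top <- alphabet[which(rk == 1)]
    oe <- oe + as.numeric(!(top %in% t))
    cov <- cov + max(rk[t]) - 1
    false <- setdiff(alphabet, t)
    if (length(false) > 0) {
      bad <- 0
      for (y in t) for (z in false) if (rk[z] < rk[y]) bad <- bad + 1
      rl <- c(rl, bad / (length(t) * length(false)))
    }
    prec <- 0
    for (y in t) {
      above <- 0
      for (y2 in t) if (rk[y2] <= rk[y]) above <- above + 1
      prec <- prec + above / rk[y]
    }
    ap <- ap + prec / length(t)
  }
  c(subset_accuracy = unname(sa / n), hamming_loss = unname(hl / n),
    one_error = unname(oe / n), coverage = unname(cov / n),
    ranking_loss = unname(mean(rl)), average_precision = unname(ap / n))
}

# small random multi-label dataset built directly (independent of the
# package generator)
random_toy_dataset <- function(n, m, alphabet, seed) {
  set.seed(seed)
  X <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  colnames(X) <- paste0("x", seq_len(m))
  sets <- lapply(seq_len(n), function(i) {
    k <- sample(seq_along(alphabet), 1)
    sample(alphabet, k)
  })
  ml_dataset(X, sets, alphabet = alphabet)
}
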