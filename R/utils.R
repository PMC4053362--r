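# pairwise distances between the rows of two binary matrices
cross_dist <- function(A, B, metric = c("euclidean", "hamming")) {
  metric <- match.arg(metric)
  A <- as.matrix(A)
  B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0 # guard against float noise
  if (metric == "hamming") d2 else sqrt(d2)
}

# feature matrix from an ml_dataset/pt5_df, a data frame, or a bare matrix
as_feature_matrix <- function(newdata, feature_cols) {
  if (inherits(newdata, "ml_dataset") || inherits(newdata, "pt5_df")) {
    return(ml_features(newdata))
  }
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(feature_cols %in% colnames(X))) {
    X <- X[, feature_cols, drop = FALSE]
  }
  if (ncol(X) != length(feature_cols)) {
    abort("newdata does not match the training features",
          class = "mlcp_shape_error")
  }
  colnames(X) <- feature_cols
  X
}

case_ids_of <- function(newdata, n) {
  if (is.data.frame(newdata) && "case_id" %in% names(newdata)) {
    as.character(newdata$case_id)
  } else {
    as.character(seq_len(n))
  }
}
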