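# Independent oracles used across the suite. These deliberately do not call
# the implementation paths they are checking.

# brute-force O(n^3) complete-linkage agglomeration; returns the merge
# heights and the cophenetic distance matrix (labels x labels)
bf_complete_linkage <- function(x) {
  stopifnot(!is.null(rownames(x)))
  D <- as.matrix(stats::dist(x))
  labels <- rownames(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    h <- best[1]; i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- h
    coph[clusters[[j]], clusters[[i]]] <- h
    heights <- c(heights, h)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# two-sided permutation p-value for the Pearson correlation
perm_pearson_p <- function(x, y, n_perm = 10000L, seed = 42L) {
  set.seed(seed)
  r_obs <- abs(stats::cor(x, y))
  hits <- sum(vapply(seq_len(n_perm), function(i)
    abs(stats::cor(x, sample(y))) >= r_obs, logical(1)))
  (hits + 1) / (n_perm + 1)
}

# brute-force ROC AUC: sweep every distinct score threshold, build the
# confusion matrix, trapezoid over (FPR, TPR)
bf_roc_auc <- function(score, positive) {
  ths <- sort(unique(score))
  tpr <- vapply(ths, function(t) mean(score[positive] <= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(score[!positive] <= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# 95% sampling interval for a sample correlation at true rho and size n
# (Fisher z)
fisher_z_interval <- function(rho, n, conf = 0.95) {
  z <- atanh(rho)
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

# small labelled expression matrix from a plain numeric matrix
toy_matrix <- function(vals, layer = "expression",
                       units = "normalized_protein", prefix = c("s", "g")) {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("%s%02d", prefix[1], seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("%s%02d", prefix[2], seq_len(ncol(vals)))
  expression_matrix(vals, layer = layer, units = units)
}
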