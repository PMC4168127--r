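# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, full sorts, pairwise enumeration.

# k nearest neighbours by repeated minimum extraction over the full distance
# matrix, ties to the lower index.
oracle_knn <- function(m, i, k) {
  dmat <- as.matrix(dist(m))
  dv <- dmat[i, ]
  dv[i] <- Inf
  out <- integer(k)
  for (j in seq_len(k)) {
    best <- which(dv == min(dv))[1]
    out[j] <- best
    dv[best] <- Inf
  }
  out
}

# AUC by brute-force enumeration of all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Threshold-dependent metrics computed from first principles.
oracle_metrics <- function(scores, labels, t) {
  tp <- sum(scores >= t & labels == 1); fp <- sum(scores >= t & labels == -1)
  fn <- sum(scores < t & labels == 1); tn <- sum(scores < t & labels == -1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  spe <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  c(sen = sen, spe = spe, mcc = mcc)
}

# Exhaustive scan over the candidate set (midpoints plus sentinels),
# applying the documented tie rules directly.
oracle_threshold <- function(scores, labels, policy) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  best_t <- NA; best_key <- NULL
  for (t in cand) {
    m <- oracle_metrics(scores, labels, t)
    key <- if (policy == "max_mcc") c(-m[["mcc"]], -m[["spe"]], t)
           else c(abs(m[["sen"]] - m[["spe"]]), -m[["mcc"]], t)
    if (is.null(best_key) ||
        isTRUE(key[1] < best_key[1] ||
               (key[1] == best_key[1] && (key[2] < best_key[2] ||
                (key[2] == best_key[2] && key[3] < best_key[3]))))) {
      best_key <- key; best_t <- t
    }
  }
  best_t
}

# Convexity: every synthetic vector must lie in the per-coordinate box of
# its recorded parents.
expect_convex <- function(batch, parent_matrix, tol = 1e-9) {
  for (j in seq_len(nrow(batch$vectors))) {
    a <- parent_matrix[batch$parents[j, 1], ]
    b <- parent_matrix[batch$parents[j, 2], ]
    expect_true(all(batch$vectors[j, ] >= pmin(a, b) - tol &
                    batch$vectors[j, ] <= pmax(a, b) + tol))
  }
}

mock_spec <- function(fn) classifier_spec("mock", mock_fn = fn)

rand_minority <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}
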