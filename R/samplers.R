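#' Linear interpolation between two feature vectors
#'
#' `a + lam * (b - a)`, the elementary synthesis step shared by SMOTE,
#' ADASYN and supervised over-sampling.
#'
#' @param a,b numeric vectors of equal length.
#' @param lam interpolation weight in `[0, 1]`.
#' @return numeric vector of the same length as `a`.
#' @export
interpolate <- function(a, b, lam) {
  if (length(a) != length(b)) {
    abort_validation(sprintf("dimension mismatch: %d vs %d", length(a), length(b)))
  }
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1) {
    abort_validation("`lam` must be a single value in [0, 1]")
  }
  a + lam * (b - a)
}

#' @noRd
new_synthetic_batch <- function(vectors, parents, lambdas, confidences = NULL) {
  structure(list(vectors = vectors, parents = parents, lambdas = lambdas,
                 confidences = confidences),
            class = "synthetic_batch")
}

#' @noRd
empty_batch <- function(d) {
  new_synthetic_batch(matrix(numeric(0), nrow = 0L, ncol = d),
                      matrix(integer(0), nrow = 0L, ncol = 2L,
                             dimnames = list(NULL, c("parent_a", "parent_b"))),
                      numeric(0))
}

#' @export
print.synthetic_batch <- function(x, ...) {
  cat(sprintf("<synthetic_batch> %d synthetic samples x %d features%s\n",
              nrow(x$vectors), ncol(x$vectors),
              if (is.null(x$confidences)) "" else " (with confidences)"))
  invisible(x)
}

#' Export a synthetic batch as a TSV sidecar
#'
#' Columns: `parent_a`, `parent_b`, `lambda`, `confidence` (empty when the
#' sampler records none), then the `d` feature values.
#'
#' @param batch a `synthetic_batch`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_batch <- function(batch, path) {
  stopifnot(inherits(batch, "synthetic_batch"))
  d <- ncol(batch$vectors)
  conf <- if (is.null(batch$confidences)) rep(NA_real_, nrow(batch$vectors)) else batch$confidences
  df <- data.frame(parent_a = batch$parents[, 1], parent_b = batch$parents[, 2],
                   lambda = batch$lambdas, confidence = conf)
  feat <- as.data.frame(batch$vectors)
  if (d > 0) names(feat) <- sprintf("f%03d", seq_len(d))
  write.table(cbind(df, feat), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Random over-sampling (ROS)
#'
#' Augments the minority class by replicating uniformly chosen minority rows.
#' Each replicate records its source row as both parents and `lambda = 0`.
#'
#' @param minority numeric matrix of minority-class rows.
#' @param n_extra number of replicates to draw.
#' @param seed RNG seed; the call is deterministic given the seed.
#' @return a `synthetic_batch` of `n_extra` rows.
#' @export
random_oversample <- function(minority, n_extra, seed = 0L) {
  minority <- as_feature_matrix(minority, "minority")
  if (nrow(minority) < 1L) abort_validation("minority class empty")
  if (!is_count(n_extra)) abort_validation("`n_extra` must be a non-negative integer")
  if (n_extra == 0L) return(empty_batch(ncol(minority)))
  idx <- local_seed(seed, sample.int(nrow(minority), n_extra, replace = TRUE))
  new_synthetic_batch(minority[idx, , drop = FALSE],
                      cbind(parent_a = idx, parent_b = idx),
                      rep(0, n_extra))
}

#' k nearest neighbours of a row within a matrix
#'
#' Euclidean metric; the query row itself is excluded; distance ties are
#' broken by the lower row index (stable).
#'
#' @param minority numeric matrix.
#' @param i 1-based query row index.
#' @param k neighbourhood size, `1 <= k <= nrow - 1`.
#' @return integer vector of `k` row indices, nearest first.
#' @export
knn_minority <- function(minority, i, k) {
  minority <- as_feature_matrix(minority, "minority")
  n <- nrow(minority)
  if (!is_count(i, 1L) || i > n) abort_validation("query index out of range")
  if (!is_count(k, 1L) || k > n - 1L) {
    abort_validation(sprintf("k must satisfy 1 <= k <= %d, got %s", n - 1L, format(k)))
  }
  diffs <- sweep(minority, 2L, minority[i, ], "-")
  d2 <- rowSums(diffs * diffs)
  d2[i] <- Inf
  order(d2)[seq_len(k)]  # order() is stable: ties fall to the lower index
}

#' Synthetic minority over-sampling technique (SMOTE)
#'
#' Generates synthetic minority samples by interpolating each base minority
#' row toward one of its `k` nearest minority neighbours with a
#' `Uniform[0,1]` weight. Base rows are cycled round-robin in input order, so
#' per-row synthesis counts differ by at most one (SMOTE allocates the same
#' number of synthetic samples to each original minority sample); the
#' remainder goes to the earliest rows.
#'
#' RNG draw order per synthetic sample: neighbour index, then lambda.
#'
#' @param minority numeric matrix of minority rows (at least 2).
#' @param k neighbourhood size.
#' @param n_synth number of synthetic samples.
#' @param seed RNG seed.
#' @return a `synthetic_batch` of `n_synth` rows.
#' @export
smote <- function(minority, k = 5L, n_synth, seed = 0L) {
  minority <- as_feature_matrix(minority, "minority")
  n <- nrow(minority)
  if (n < 2L) abort_validation("SMOTE needs at least 2 minority samples (no neighbour exists)")
  if (!is_count(n_synth)) abort_validation("`n_synth` must be a non-negative integer")
  if (!is_count(k, 1L) || k > n - 1L) {
    abort_validation(sprintf("k must satisfy 1 <= k <= %d", n - 1L))
  }
  if (n_synth == 0L) return(empty_batch(ncol(minority)))
  base <- rep(seq_len(n), length.out = n_synth)
  nn <- lapply(seq_len(n), function(i) knn_minority(minority, i, k))
  vecs <- matrix(0, n_synth, ncol(minority))
  pa <- integer(n_synth); pb <- integer(n_synth); lam <- numeric(n_synth)
  local_seed(seed, {
    for (j in seq_len(n_synth)) {
      i <- base[j]
      nb <- nn[[i]][sample.int(k, 1L)]
      l <- runif(1)
      vecs[j, ] <- minority[i, ] + l * (minority[nb, ] - minority[i, ])
      pa[j] <- i; pb[j] <- nb; lam[j] <- l
    }
  })
  new_synthetic_batch(vecs, cbind(parent_a = pa, parent_b = pb), lam)
}

#' ADASYN synthesis plan
#'
#' Computes the adaptive allocation of synthetic samples. The total is
#' `G = round(beta * (|N| - |P|))`. For each minority row, `Delta_i` counts
#' the majority samples among its `k` nearest neighbours in the *whole*
#' training set; the weights `Delta_i / (k Z)` are normalised to sum to one
#' (`Z` is the normalisation constant). Per-row counts are
#' `g_i ~ weight_i * G`, made integral by the largest-remainder rule so they
#' sum to `G` exactly (ties to the lower index).
#'
#' If every neighbourhood is purely minority (`all Delta_i = 0`) the weight
#' definition degenerates to 0/0; the plan then falls back to uniform weights,
#' i.e. the SMOTE allocation.
#'
#' @param minority,majority numeric matrices of the two classes.
#' @param beta balance level in `(0, 1]`; `beta = 1` targets full balance.
#' @param k neighbourhood size in the whole training set.
#' @return an object of class `adasyn_plan`: list with `total_g`, `weights`,
#'   `counts`, `delta` and `z`.
#' @export
adasyn_plan <- function(minority, majority, beta = 1, k = 5L) {
  minority <- as_feature_matrix(minority, "minority")
  majority <- as_feature_matrix(majority, "majority")
  if (nrow(minority) < 1L) abort_validation("minority class empty")
  if (nrow(majority) < 1L) abort_validation("majority class empty")
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    abort_validation("`beta` must lie in (0, 1]")
  }
  np <- nrow(minority); nn <- nrow(majority); ntot <- np + nn
  if (!is_count(k, 1L) || k > ntot - 1L) {
    abort_validation(sprintf("k must satisfy 1 <= k <= %d", ntot - 1L))
  }
  if (nn <= np) {
    warning("majority class not larger than minority; nothing to balance (G = 0)")
    g_total <- 0L
  } else {
    g_total <- as.integer(round(beta * (nn - np)))
  }
  whole <- rbind(minority, majority)
  is_major <- c(rep(FALSE, np), rep(TRUE, nn))
  delta <- vapply(seq_len(np), function(i) {
    sum(is_major[knn_minority(whole, i, k)])
  }, numeric(1))
  z <- sum(delta / k)
  if (z == 0) {
    weights <- rep(1 / np, np)   # degenerate-Z fallback: uniform allocation
    z <- NA_real_
  } else {
    weights <- (delta / k) / z
  }
  counts <- largest_remainder(weights * g_total, g_total)
  structure(list(total_g = g_total, weights = weights, counts = counts,
                 delta = delta, z = z, k = as.integer(k), beta = beta),
            class = "adasyn_plan")
}

#' Largest-remainder integer apportionment
#' @noRd
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- x - base
    extra <- order(-frac)[seq_len(rem)]  # stable: ties to the lower index
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Adaptive synthetic sampling (ADASYN)
#'
#' Executes an [adasyn_plan()]: for each minority row `i`, synthesises the
#' planned `g_i` samples by interpolating toward its `k` nearest neighbours
#' *within the minority set* (the density estimate of the plan uses the whole
#' training set; synthesis is minority-only, as in SMOTE). The synthesis
#' neighbourhood size is capped at `|P| - 1`.
#'
#' RNG draw order: minority rows in input order; per sample, neighbour index
#' then lambda.
#'
#' @inheritParams adasyn_plan
#' @param seed RNG seed.
#' @param plan optionally a precomputed [adasyn_plan()] for these inputs.
#' @return a `synthetic_batch` of exactly `plan$total_g` rows.
#' @export
adasyn <- function(minority, majority, beta = 1, k = 5L, seed = 0L, plan = NULL) {
  minority <- as_feature_matrix(minority, "minority")
  if (is.null(plan)) plan <- adasyn_plan(minority, majority, beta, k)
  stopifnot(inherits(plan, "adasyn_plan"))
  d <- ncol(minority)
  if (plan$total_g == 0L) return(empty_batch(d))
  n <- nrow(minority)
  if (n < 2L) abort_validation("ADASYN synthesis needs at least 2 minority samples")
  k_syn <- min(plan$k, n - 1L)
  nn <- lapply(seq_len(n), function(i) knn_minority(minority, i, k_syn))
  m <- plan$total_g
  vecs <- matrix(0, m, d)
  pa <- integer(m); pb <- integer(m); lam <- numeric(m)
  local_seed(seed, {
    j <- 0L
    for (i in seq_len(n)) {
      gi <- plan$counts[i]
      if (gi == 0L) next
      for (r in seq_len(gi)) {
        j <- j + 1L
        nb <- nn[[i]][sample.int(k_syn, 1L)]
        l <- runif(1)
        vecs[j, ] <- minority[i, ] + l * (minority[nb, ] - minority[i, ])
        pa[j] <- i; pb[j] <- nb; lam[j] <- l
      }
    }
  })
  new_synthetic_batch(vecs, cbind(parent_a = pa, parent_b = pb), lam)
}
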