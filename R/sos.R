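#' Supervised over-sampling configuration
#'
#' @param alpha over-sampling coefficient (>= 1): target minority size after
#'   over-sampling divided by the original minority size. `NULL` (default)
#'   resolves at run time to `|N| / |P|`, i.e. synthesis to full balance.
#' @param c_low,c_high confidence interval bounds, `0 <= c_low < c_high <= 1`.
#'   A synthesised sample is accepted iff its minority-class confidence under
#'   the initial model lies in `[c_low, c_high]`. The upper bound exists
#'   because near-certain samples behave like replicated ("tied") minority
#'   points and invite over-fitting. The defaults `[0.5, 0.95]` are this
#'   package's choice, not a published value.
#' @param max_attempts cap on synthesis attempts before giving up with an
#'   error; `NULL` resolves to `200 * n_target`.
#' @param seed RNG seed.
#' @return an object of class `sos_config`.
#' @export
sos_config <- function(alpha = NULL, c_low = 0.5, c_high = 0.95,
                       max_attempts = NULL, seed = 0L) {
  if (!is.null(alpha) && (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1)) {
    abort_validation("`alpha` must be a single value >= 1")
  }
  if (!is.numeric(c_low) || !is.numeric(c_high) ||
      c_low < 0 || c_low >= c_high || c_high > 1) {
    abort_validation("confidence interval must satisfy 0 <= c_low < c_high <= 1")
  }
  if (!is.null(max_attempts) && !is_count(max_attempts, 1L)) {
    abort_validation("`max_attempts` must be a positive integer")
  }
  structure(list(alpha = alpha, c_low = c_low, c_high = c_high,
                 max_attempts = max_attempts, seed = seed),
            class = "sos_config")
}

#' Supervised over-sampling (SOS)
#'
#' Synthesises minority-class samples under the supervision of a classifier
#' trained on the original data:
#'
#' 1. *Step I* — fit an initial model `CM` on the unmodified dataset.
#' 2. *Step II* — repeatedly draw two distinct minority rows uniformly at
#'    random, interpolate them with `lambda ~ Uniform[0,1]`, and compute the
#'    candidate's minority-class confidence under `CM`. The candidate is
#'    accepted iff the confidence lies in `[c_low, c_high]`. The loop stops
#'    after `n_target = ceiling((alpha - 1) * |P|)` acceptances.
#'
#' The majority class is returned untouched; accepted samples are appended
#' with label `+1`. The RNG stream is consumed strictly in the order
#' (index pair, then lambda) per proposal, so runs are reproducible and
#' replayable from the seed. If `max_attempts` proposals are exhausted before
#' `n_target` acceptances, an error of class `sosampler_attempt_cap` reports
#' the observed acceptance rate and the interval (the caller may widen it).
#'
#' @param dataset a [labeled_dataset()]; label `+1` marks the minority class.
#' @param spec a [classifier_spec()] for the supervising model.
#' @param cfg an [sos_config()].
#' @return list with `augmented` (a [labeled_dataset()]), `batch` (a
#'   `synthetic_batch` whose `confidences` are the accepted samples'
#'   confidences) and `model` (the initial `sos_model`).
#' @examples
#' ds <- gen_imbalanced(n_min = 15, n_maj = 60, d = 3, separation = 3, seed = 1)
#' mock <- classifier_spec("mock", mock_fn = function(x) 0.7)
#' out <- sos(ds, mock, sos_config(alpha = 2, seed = 1))
#' sum(out$augmented$labels == 1)  # 30: minority doubled
#' @export
sos <- function(dataset, spec, cfg = sos_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "classifier_spec"),
            inherits(cfg, "sos_config"))
  parts <- split_by_class(dataset)
  P <- parts$minority
  np <- nrow(P)
  alpha <- if (is.null(cfg$alpha)) nrow(parts$majority) / np else cfg$alpha
  if (alpha < 1) alpha <- 1
  n_target <- as.integer(ceiling((alpha - 1) * np))
  model <- grid_search_fit(dataset, spec)
  if (n_target == 0L) {
    return(list(augmented = dataset, batch = empty_batch(ncol(P)), model = model))
  }
  if (np < 2L) abort_validation("SOS needs at least 2 minority samples to interpolate")
  max_attempts <- if (is.null(cfg$max_attempts)) 200L * n_target else as.integer(cfg$max_attempts)

  pos_rows <- which(dataset$labels == 1)
  acc_vecs <- matrix(NA_real_, n_target, ncol(P))
  acc_pa <- integer(n_target); acc_pb <- integer(n_target)
  acc_lam <- numeric(n_target); acc_conf <- numeric(n_target)
  n_acc <- 0L; attempts <- 0L
  chunk <- min(max(2L * n_target, 64L), 4096L)

  local_seed(cfg$seed, {
    while (n_acc < n_target && attempts < max_attempts) {
      m <- min(chunk, max_attempts - attempts)
      pa <- integer(m); pb <- integer(m); lam <- numeric(m)
      vecs <- matrix(0, m, ncol(P))
      for (j in seq_len(m)) {
        pr <- sample.int(np, 2L)           # distinct indices
        l <- runif(1)
        pa[j] <- pr[1]; pb[j] <- pr[2]; lam[j] <- l
        vecs[j, ] <- P[pr[1], ] + l * (P[pr[2], ] - P[pr[1], ])
      }
      conf <- confidence(model, vecs)      # consumes no RNG
      for (j in seq_len(m)) {
        attempts <- attempts + 1L
        if (conf[j] >= cfg$c_low && conf[j] <= cfg$c_high) {
          n_acc <- n_acc + 1L
          acc_vecs[n_acc, ] <- vecs[j, ]
          acc_pa[n_acc] <- pa[j]; acc_pb[n_acc] <- pb[j]
          acc_lam[n_acc] <- lam[j]; acc_conf[n_acc] <- conf[j]
          if (n_acc == n_target) break
        }
      }
    }
  })
  if (n_acc < n_target) {
    stop(structure(class = c("sosampler_attempt_cap", "error", "condition"),
                   list(message = sprintf(
      paste0("SOS attempt cap reached: %d acceptances in %d attempts ",
             "(rate %.4f) for interval [%g, %g]; widen the interval or raise max_attempts"),
      n_acc, attempts, n_acc / attempts, cfg$c_low, cfg$c_high),
      call = sys.call(-1))))
  }
  batch <- new_synthetic_batch(acc_vecs,
                               cbind(parent_a = acc_pa, parent_b = acc_pb),
                               acc_lam, acc_conf)
  augmented <- labeled_dataset(rbind(dataset$features, acc_vecs),
                               c(dataset$labels, rep(1, n_target)))
  # record where the original minority rows sit, for provenance
  attr(batch, "minority_rows") <- pos_rows
  list(augmented = augmented, batch = batch, model = model)
}

#' Apply a named over-sampler to a dataset
#'
#' Convenience dispatcher used by the cross-validation harness and the CLI.
#' `"ros"`, `"smote"` and `"adasyn"` default to synthesising to full balance;
#' `"sos"` uses the alpha in its config (also full balance by default).
#'
#' @param dataset a [labeled_dataset()].
#' @param sampler one of `"none"`, `"ros"`, `"smote"`, `"adasyn"`, `"sos"`.
#' @param seed RNG seed.
#' @param k neighbourhood size for SMOTE/ADASYN.
#' @param beta ADASYN balance level.
#' @param sos_cfg an [sos_config()] (SOS only).
#' @param spec a [classifier_spec()] (SOS only, for the supervising model).
#' @return list with `dataset` (augmented) and `batch` (`synthetic_batch`,
#'   empty for `"none"`).
#' @export
apply_sampler <- function(dataset, sampler = c("none", "ros", "smote", "adasyn", "sos"),
                          seed = 0L, k = 5L, beta = 1,
                          sos_cfg = sos_config(seed = seed), spec = NULL) {
  sampler <- match.arg(sampler)
  parts <- if (sampler != "none") split_by_class(dataset) else NULL
  if (sampler == "none") {
    return(list(dataset = dataset, batch = empty_batch(ncol(dataset$features))))
  }
  np <- nrow(parts$minority); nn <- nrow(parts$majority)
  deficit <- max(nn - np, 0L)
  if (sampler == "ros") {
    batch <- random_oversample(parts$minority, deficit, seed = seed)
  } else if (sampler == "smote") {
    batch <- smote(parts$minority, k = min(k, np - 1L), n_synth = deficit, seed = seed)
  } else if (sampler == "adasyn") {
    batch <- adasyn(parts$minority, parts$majority, beta = beta, k = k, seed = seed)
  } else {
    if (is.null(spec)) abort_validation("SOS requires a classifier spec")
    out <- sos(dataset, spec, sos_cfg)
    return(list(dataset = out$augmented, batch = out$batch, model = out$model))
  }
  augmented <- labeled_dataset(rbind(dataset$features, batch$vectors),
                               c(dataset$labels, rep(1, nrow(batch$vectors))))
  list(dataset = augmented, batch = batch)
}
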