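#' Group-aware k-fold assignment
#'
#' When `groups` is given, whole groups (e.g. proteins) are shuffled with the
#' seed and dealt round-robin to folds, so all residues of a protein share a
#' fold. Otherwise folds are stratified at the sample level.
#'
#' @param labels label vector over `{+1,-1}`.
#' @param groups optional per-sample group ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per sample.
#' @export
make_folds <- function(labels, groups = NULL, k = 5L, seed = 0L) {
  if (!is_count(k, 2L)) abort_validation("k must be an integer >= 2")
  if (is.null(groups)) return(stratified_folds(labels, k, seed))
  if (length(groups) != length(labels)) abort_validation("groups/labels length mismatch")
  ug <- unique(groups)
  if (length(ug) < k) {
    abort_validation(sprintf("fewer groups (%d) than folds (%d)", length(ug), k))
  }
  perm <- local_seed(seed, sample(ug))
  fold_of_group <- stats::setNames(rep_len(seq_len(k), length(ug)), perm)
  as.integer(fold_of_group[as.character(groups)])
}

#' Cross-validated evaluation with optional in-fold over-sampling
#'
#' Runs `k`-fold cross-validation of the classifier described by `spec`,
#' optionally applying an over-sampler to the *training portion of each fold
#' only* — test folds never contain synthetic samples. Folds are
#' protein-level when `groups` is given (all residues of a protein share a
#' fold, preventing homologous-window leakage), else stratified sample-level.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param groups optional per-sample group (protein) ids.
#' @param sampler over-sampler applied to training folds; see
#'   [apply_sampler()].
#' @param k number of folds (default 5).
#' @param policy threshold policy for reporting; see [select_threshold()].
#' @param seed RNG seed; fold assignment and per-fold sampler seeds derive
#'   from it.
#' @param k_nn neighbourhood size for SMOTE/ADASYN.
#' @param beta ADASYN balance level.
#' @param sos_cfg an [sos_config()] used when `sampler = "sos"` (its seed is
#'   overridden per fold).
#' @return object of class `cv_report`: list with `folds` (per-fold metric
#'   data frame), `pooled` (metrics of the pooled scores), `scores`
#'   (per-sample data frame with fold, group, label, score) and `config`.
#' @export
cross_validate <- function(dataset, spec, groups = NULL,
                           sampler = "none", k = 5L, policy = "max_mcc",
                           seed = 0L, k_nn = 5L, beta = 1,
                           sos_cfg = sos_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  fold <- make_folds(dataset$labels, groups, k, seed)
  all_scores <- numeric(nrow(dataset$features))
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    train <- labeled_dataset(dataset$features[!te, , drop = FALSE],
                             dataset$labels[!te])
    fold_seed <- (as.integer(seed) + 7919L * f) %% .Machine$integer.max
    cfg_f <- sos_cfg; cfg_f$seed <- fold_seed
    aug <- apply_sampler(train, sampler, seed = fold_seed, k = k_nn,
                         beta = beta, sos_cfg = cfg_f, spec = spec)
    model <- grid_search_fit(aug$dataset, spec)
    s <- confidence(model, dataset$features[te, , drop = FALSE])
    all_scores[te] <- s
    ev <- evaluate_predictions(s, dataset$labels[te], policy)
    fold_rows[[f]] <- data.frame(fold = f, n_test = sum(te),
                                 n_synth = nrow(aug$batch$vectors), t(ev))
  }
  folds <- do.call(rbind, fold_rows)
  pooled <- evaluate_predictions(all_scores, dataset$labels, policy)
  structure(list(folds = folds, pooled = pooled,
                 scores = data.frame(fold = fold,
                                     group = if (is.null(groups)) NA else groups,
                                     label = dataset$labels, score = all_scores),
                 config = list(sampler = sampler, k = k, policy = policy,
                               seed = seed, k_nn = k_nn, beta = beta)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, sampler = %s, policy = %s\n",
              x$config$k, x$config$sampler, x$config$policy))
  cat("pooled: ", paste(sprintf("%s = %.4f", names(x$pooled), x$pooled),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write a cross-validation report to TSV and JSON
#'
#' `<prefix>_folds.tsv` holds the per-fold metrics, `<prefix>_report.json`
#' the pooled metrics plus configuration (seed included), and
#' `<prefix>_roc.tsv` the pooled ROC points.
#'
#' @param report a `cv_report`.
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_cv_report <- function(report, prefix) {
  stopifnot(inherits(report, "cv_report"))
  paths <- c(folds = paste0(prefix, "_folds.tsv"),
             json = paste0(prefix, "_report.json"),
             roc = paste0(prefix, "_roc.tsv"))
  write.table(report$folds, paths[["folds"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(pooled = as.list(report$pooled),
                            config = report$config),
                       paths[["json"]], auto_unbox = TRUE, digits = NA)
  roc <- roc_points(report$scores$score, report$scores$label)
  write.table(roc, paths[["roc"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
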