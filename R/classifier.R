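#' Classifier specification
#'
#' Describes the probabilistic classifier used both to filter supervised
#' over-sampling proposals and to score residues in the prediction pipeline.
#'
#' Two kinds are available:
#' \describe{
#'   \item{`gaussian`}{a Gaussian-kernel classifier: ridge-penalised kernel
#'     logistic regression fitted with the glmnet engine. The cost `C` plays
#'     the usual inverse-regularisation role (`lambda = 1/(n C)`) and `gamma`
#'     is the kernel width of `exp(-gamma ||x - x'||^2)`. Hyperparameters are
#'     chosen by stratified cross-validated grid search maximising mean MCC.}
#'   \item{`mock`}{a deterministic test double whose confidence is computed by
#'     `mock_fn(x)`; required for reproducible tests of the sampling loop.}
#' }
#'
#' Default grids follow the customary libsvm-style ranges:
#' `C in 2^{-5, -1, 3, 7, 11, 15}`, `gamma in 2^{-15, -11, -7, -3, 1, 3}`.
#'
#' @param kind `"gaussian"` or `"mock"`.
#' @param c_grid positive cost values to search.
#' @param gamma_grid positive kernel widths to search.
#' @param cv_folds folds for the hyperparameter search (default 10).
#' @param seed RNG seed for fold assignment.
#' @param mock_fn for `kind = "mock"`: function mapping a feature vector (or
#'   row-matrix) to a confidence in `[0, 1]`.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("gaussian", "mock"),
                            c_grid = 2^c(-5, -1, 3, 7, 11, 15),
                            gamma_grid = 2^c(-15, -11, -7, -3, 1, 3),
                            cv_folds = 10L, seed = 0L, mock_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (length(c_grid) < 1L || any(c_grid <= 0)) abort_validation("`c_grid` must be positive")
    if (length(gamma_grid) < 1L || any(gamma_grid <= 0)) abort_validation("`gamma_grid` must be positive")
    if (!is_count(cv_folds, 2L)) abort_validation("`cv_folds` must be an integer >= 2")
  } else if (!is.function(mock_fn)) {
    abort_validation("mock classifier requires `mock_fn`")
  }
  structure(list(kind = kind, c_grid = sort(c_grid), gamma_grid = sort(gamma_grid),
                 cv_folds = as.integer(cv_folds), seed = seed, mock_fn = mock_fn),
            class = "classifier_spec")
}

#' @noRd
gaussian_kernel <- function(A, B, gamma) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit ridge-penalised kernel logistic regression via glmnet.
#' Returns intercept + dual-style coefficients over the training rows.
#' @noRd
fit_klr <- function(X, y, C, gamma) {
  n <- nrow(X)
  K <- gaussian_kernel(X, X, gamma)
  lam <- 1 / (C * n)
  yf <- factor(y, levels = c(-1, 1))
  fit <- withCallingHandlers(
    glmnet::glmnet(K, yf, family = "binomial", alpha = 0,
                   lambda = lam * c(16, 8, 4, 2, 1),
                   standardize = FALSE, maxit = 1e5),
    warning = function(w) {
      # tiny-class advisory from the engine; expected at toy sample sizes
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  b <- as.numeric(coef(fit, s = lam, exact = FALSE))
  list(b0 = b[1], beta = b[-1], gamma = gamma, C = C, X_train = X)
}

#' @noRd
klr_scores <- function(engine, X) {
  K <- gaussian_kernel(X, engine$X_train, engine$gamma)
  as.numeric(1 / (1 + exp(-(engine$b0 + K %*% engine$beta))))
}

#' Stratified fold assignment (deterministic given seed)
#' @noRd
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit a classifier by cross-validated grid search
#'
#' For the Gaussian-kernel classifier, every `(C, gamma)` pair in the grids is
#' scored by stratified `cv_folds`-fold cross-validation on the training data;
#' the score is the mean fold MCC of the 0.5-thresholded probabilities. The
#' best pair (ties broken toward smaller `C`, then smaller `gamma`) is refitted
#' on all data. If the smaller class has fewer members than `cv_folds` the
#' fold count is reduced with a warning; with a single grid pair the search is
#' skipped entirely.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @return an object of class `sos_model` with elements `kind`, `engine`,
#'   `meta` (chosen `C`, `gamma`, per-pair mean CV MCC) and `d`.
#' @export
grid_search_fit <- function(dataset, spec) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "classifier_spec"))
  d <- ncol(dataset$features)
  if (spec$kind == "mock") {
    return(structure(list(kind = "mock", engine = spec$mock_fn, d = d,
                          meta = list()), class = "sos_model"))
  }
  y <- dataset$labels
  npos <- sum(y == 1); nneg <- sum(y == -1)
  if (npos == 0L || nneg == 0L) abort_validation("both classes must be present to fit")
  grid <- expand.grid(C = spec$c_grid, gamma = spec$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  cv_scores <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    k <- min(spec$cv_folds, npos, nneg)
    if (k < spec$cv_folds) {
      warning(sprintf("reducing cv_folds from %d to %d (smallest class has %d members)",
                      spec$cv_folds, k, min(npos, nneg)))
    }
    if (k < 2L) abort_validation("too few samples in the smaller class for a grid search")
    fold <- stratified_folds(y, k, spec$seed)
    X <- dataset$features
    for (g in seq_len(nrow(grid))) {
      mccs <- vapply(seq_len(k), function(f) {
        tr <- fold != f
        eng <- fit_klr(X[tr, , drop = FALSE], y[tr], grid$C[g], grid$gamma[g])
        s <- klr_scores(eng, X[!tr, , drop = FALSE])
        metrics(confusion(s, y[!tr], 0.5))[["mcc"]]
      }, numeric(1))
      cv_scores[g] <- mean(mccs)
    }
    best <- which.max(cv_scores)  # grid pre-sorted: ties fall to smaller C then gamma
  } else {
    best <- 1L
  }
  engine <- fit_klr(dataset$features, y, grid$C[best], grid$gamma[best])
  structure(list(kind = "gaussian", engine = engine, d = d,
                 meta = list(C = grid$C[best], gamma = grid$gamma[best],
                             grid = cbind(grid, cv_mcc = cv_scores))),
            class = "sos_model")
}

#' @export
print.sos_model <- function(x, ...) {
  if (x$kind == "mock") {
    cat("<sos_model> mock classifier\n")
  } else {
    cat(sprintf("<sos_model> Gaussian-kernel classifier (C = %g, gamma = %g, n_train = %d)\n",
                x$meta$C, x$meta$gamma, nrow(x$engine$X_train)))
  }
  invisible(x)
}

#' Minority-class confidence of one or more samples
#'
#' Probability-like score in `[0, 1]` that each row belongs to the minority
#' (`+1`) class, monotone in the engine's decision value.
#'
#' @param model an `sos_model` from [grid_search_fit()].
#' @param x numeric vector (one sample) or matrix (one row per sample).
#' @return numeric vector of confidences in `[0, 1]`.
#' @export
confidence <- function(model, x) {
  stopifnot(inherits(model, "sos_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$d) {
    abort_validation(sprintf("dimension mismatch: model expects %d features, got %d",
                             model$d, ncol(x)))
  }
  if (model$kind == "mock") {
    s <- vapply(seq_len(nrow(x)), function(i) as.numeric(model$engine(x[i, ])), numeric(1))
  } else {
    s <- klr_scores(model$engine, x)
  }
  pmin(pmax(s, 0), 1)
}

#' Save a fitted Gaussian-kernel model to a portable JSON file
#'
#' Stores a format version, hyperparameters, intercept, coefficients and the
#' training matrix (needed to evaluate the kernel on new points). Mock models
#' hold an arbitrary R function and are not serialisable.
#'
#' @param model an `sos_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sos_model"))
  if (model$kind != "gaussian") abort_validation("only Gaussian-kernel models can be saved")
  obj <- list(format = "sosampler_model", version = 1L, kind = model$kind,
              d = model$d, C = model$meta$C, gamma = model$meta$gamma,
              b0 = model$engine$b0, beta = model$engine$beta,
              X_train = model$engine$X_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model written by [save_model()]
#' @param path path to the JSON file.
#' @return an `sos_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "sosampler_model") {
    abort_validation(sprintf("not a sosampler model file: %s", path))
  }
  engine <- list(b0 = obj$b0, beta = obj$beta, gamma = obj$gamma, C = obj$C,
                 X_train = matrix(obj$X_train, ncol = obj$d))
  structure(list(kind = "gaussian", engine = engine, d = obj$d,
                 meta = list(C = obj$C, gamma = obj$gamma)),
            class = "sos_model")
}
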