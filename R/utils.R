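#' @noRd
abort_validation <- function(msg, class = "sosampler_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("`seed` must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

#' @noRd
as_feature_matrix <- function(x, what = "features") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.numeric(x)) abort_validation(sprintf("%s must be numeric", what))
  if (anyNA(x) || any(!is.finite(x))) {
    abort_validation(sprintf("%s must be finite (no NA/Inf)", what))
  }
  storage.mode(x) <- "double"
  x
}
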