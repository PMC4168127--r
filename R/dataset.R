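#' Labeled feature dataset
#'
#' The basic container consumed by all samplers and classifiers: an
#' `n x d` numeric feature matrix together with a label vector over
#' `{+1, -1}`. By convention the *minority* (positive, e.g. binding-residue)
#' class is `+1` and the majority class is `-1`.
#'
#' @param features numeric matrix (or data frame) with one row per sample.
#' @param labels numeric vector of `+1`/`-1` labels, one per row.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features` (double matrix) and `labels` (double vector in `{+1,-1}`).
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), ncol = 2), rep(c(1, -1), 5))
#' table(d$labels)
#' @export
labeled_dataset <- function(features, labels) {
  features <- as_feature_matrix(features)
  labels <- as.numeric(labels)
  if (nrow(features) < 1L || ncol(features) < 1L) {
    abort_validation("dataset needs at least one sample and one feature")
  }
  if (length(labels) != nrow(features)) {
    abort_validation(sprintf(
      "labels length (%d) does not match number of rows (%d)",
      length(labels), nrow(features)))
  }
  if (!all(labels %in% c(-1, 1))) {
    abort_validation("labels must be drawn from {+1, -1}")
  }
  structure(list(features = features, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (minority %d, majority %d)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Split a dataset into minority and majority feature matrices
#'
#' Partitions the rows of a [labeled_dataset()] by label: `+1` rows form the
#' minority set P, `-1` rows the majority set N. Row order within each part is
#' preserved.
#'
#' @param dataset a [labeled_dataset()].
#' @return list with elements `minority` and `majority`, each a feature matrix.
#' @export
split_by_class <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pos <- dataset$labels == 1
  if (!any(pos)) abort_validation("minority class empty")
  if (all(pos)) abort_validation("majority class empty")
  list(minority = dataset$features[pos, , drop = FALSE],
       majority = dataset$features[!pos, , drop = FALSE])
}

#' Read a labeled feature table from delimited text
#'
#' Expects `d` numeric feature columns followed by a final label column in
#' `{+1, -1}`. A header row is auto-detected (any non-numeric cell in the
#' first line). Leading non-numeric columns (e.g. protein id provenance
#' written by [write_feature_table()]) are split off and returned as
#' `metadata`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return list with `dataset` (a [labeled_dataset()]) and `metadata`
#'   (data frame of non-numeric leading columns, or `NULL`).
#' @export
read_labeled_table <- function(path, sep = "\t") {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- read.table(path, sep = sep, header = has_header,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) abort_validation("table has no rows")
  numeric_cols <- vapply(df, is.numeric, logical(1))
  # provenance columns: known names plus the leading non-numeric block
  known_meta <- names(df) %in% c("protein_id", "residue_index")
  numeric_cols <- numeric_cols & !known_meta
  meta_idx <- which(!numeric_cols)
  if (length(meta_idx) > 0 && any(meta_idx > min(which(numeric_cols)))) {
    abort_validation("non-numeric columns must precede all feature columns")
  }
  meta <- if (length(meta_idx)) df[, meta_idx, drop = FALSE] else NULL
  num <- df[, numeric_cols, drop = FALSE]
  if (ncol(num) < 2L) abort_validation("need at least one feature column and a label column")
  labels <- num[[ncol(num)]]
  feats <- as.matrix(num[, -ncol(num), drop = FALSE])
  list(dataset = labeled_dataset(feats, labels), metadata = meta)
}

#' Write a labeled feature table as delimited text
#'
#' Inverse of [read_labeled_table()]: feature columns then a `label` column.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @param metadata optional data frame of leading provenance columns.
#' @param sep field separator.
#' @param header write a header row?
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(dataset, path, metadata = NULL, sep = "\t",
                                header = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  d <- ncol(dataset$features)
  df <- as.data.frame(dataset$features)
  names(df) <- sprintf("f%03d", seq_len(d))
  df$label <- dataset$labels
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(df))
    df <- cbind(metadata, df)
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Compositions of the nucleotide-binding benchmark datasets
#'
#' Published per-ligand sample counts for the ATP168 and NUC5 benchmark
#' collections: number of sequences, binding (positive) and non-binding
#' (negative) residues for the cross-validation split and, where available,
#' the independent validation split. The imbalance ratio is recomputed as
#' `round(num_neg / num_pos)`.
#'
#' @return data frame with columns `dataset`, `ligand`, `split`, `n_seq`,
#'   `num_pos`, `num_neg`, `printed_ratio` and recomputed `ratio`.
#' @export
benchmark_composition <- function() {
  path <- system.file("extdata", "benchmark_composition.tsv",
                      package = "sosampler", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$ratio <- as.integer(round(df$num_neg / df$num_pos))
  df
}
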