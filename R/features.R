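AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Per-protein profile
#'
#' Bundles everything the feature pipeline needs for one protein: the
#' sequence, the raw PSI-BLAST position-specific scoring matrix (L x 20
#' log-odds scores), the predicted secondary-structure probabilities
#' (L x 3, coil/helix/strand), and the binding annotation.
#'
#' @param id protein identifier.
#' @param sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @param pssm L x 20 numeric matrix of raw log-odds scores.
#' @param ss_probs L x 3 numeric matrix; rows must sum to 1 within 0.02
#'   (secondary-structure predictors print 3 decimals).
#' @param binding_idx integer vector of 1-based binding residue positions.
#' @return an object of class `protein_profile`.
#' @export
protein_profile <- function(id, sequence, pssm, ss_probs, binding_idx = integer(0)) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) abort_validation("empty sequence")
  letters_ok <- strsplit(sequence, "")[[1]] %in% c(AA20, "X")
  if (!all(letters_ok)) {
    abort_validation(sprintf("sequence contains invalid residue letter(s): %s",
                             paste(unique(strsplit(sequence, "")[[1]][!letters_ok]), collapse = "")))
  }
  pssm <- as_feature_matrix(pssm, "pssm")
  ss_probs <- as_feature_matrix(ss_probs, "ss_probs")
  if (nrow(pssm) != L || ncol(pssm) != 20L) {
    abort_validation(sprintf("pssm must be %d x 20, got %d x %d", L, nrow(pssm), ncol(pssm)))
  }
  if (nrow(ss_probs) != L || ncol(ss_probs) != 3L) {
    abort_validation(sprintf("ss_probs must be %d x 3, got %d x %d", L, nrow(ss_probs), ncol(ss_probs)))
  }
  if (any(abs(rowSums(ss_probs) - 1) > 0.02)) {
    abort_validation("ss_probs rows must sum to 1 (within 0.02)")
  }
  binding_idx <- as.integer(binding_idx)
  if (length(binding_idx) && (any(binding_idx < 1L) || any(binding_idx > L))) {
    abort_validation("binding indices out of range")
  }
  mask <- rep(FALSE, L); mask[binding_idx] <- TRUE
  structure(list(id = id, sequence = sequence, pssm = pssm, ss_probs = ss_probs,
                 binding_mask = mask),
            class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s: %d residues, %d binding\n",
              x$id, nchar(x$sequence), sum(x$binding_mask)))
  invisible(x)
}

#' Read a single-record FASTA file
#' @param path FASTA file path.
#' @return list with `id` (first word of the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[1], ">")) {
    abort_validation(sprintf("not a FASTA file: %s", path))
  }
  headers <- which(startsWith(lines, ">"))
  if (length(headers) > 1L) {
    warning("multi-record FASTA; using the first record")
    lines <- lines[seq_len(headers[2] - 1L)]
  }
  id <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]][1]
  list(id = id, sequence = toupper(paste(lines[-1], collapse = "")))
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the checkpoint-style matrix written by PSI-BLAST's `-Q` option:
#' a few header lines, then one row per residue carrying the residue index,
#' the residue letter, 20 integer log-odds scores, 20 weighted-percentage
#' columns and two trailing statistics. Only the first 20 numeric columns
#' (the log-odds block) are returned, in file column order.
#'
#' @param path path to the PSSM file.
#' @param sequence optional amino-acid string; when given, row letters are
#'   cross-checked against it.
#' @return L x 20 numeric matrix.
#' @export
parse_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path)
  rows <- list(); letters_seen <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 2L) next
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Za-z]$", tok[2])) next
    if (length(tok) < 22L) {
      abort_validation(sprintf("PSSM row at line %d has %d columns, expected >= 22",
                               ln, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      abort_validation(sprintf("non-numeric PSSM cell at line %d", ln))
    }
    rows[[length(rows) + 1L]] <- vals
    letters_seen <- c(letters_seen, toupper(tok[2]))
  }
  if (length(rows) == 0L) abort_validation(sprintf("no PSSM rows found in %s", path))
  m <- do.call(rbind, rows)
  colnames(m) <- AA20
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != nrow(m)) {
      abort_validation(sprintf("PSSM has %d rows but sequence has %d residues",
                               nrow(m), nchar(sequence)))
    }
    seq_letters <- strsplit(sequence, "")[[1]]
    bad <- which(letters_seen != seq_letters & seq_letters != "X" & letters_seen != "X")
    if (length(bad)) {
      abort_validation(sprintf("PSSM residue letters disagree with sequence at position(s) %s",
                               paste(head(bad, 5), collapse = ", ")))
    }
  }
  m
}

#' Parse a PSIPRED VFORMAT .ss2 file
#'
#' Rows carry the residue index, residue letter, predicted state letter and
#' the three class probabilities in coil, helix, strand order.
#'
#' @param path path to the `.ss2` file.
#' @return L x 3 numeric matrix with columns `C`, `H`, `E`.
#' @export
parse_ss2 <- function(path) {
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    tok <- strsplit(raw, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) next
    if (length(tok) != 6L) {
      abort_validation(sprintf("malformed .ss2 row at line %d (%d fields, expected 6)",
                               ln, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(tok[4:6]))
    if (anyNA(vals)) abort_validation(sprintf("non-numeric probability at line %d", ln))
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) abort_validation(sprintf("no residue rows in %s", path))
  m <- do.call(rbind, rows)
  colnames(m) <- c("C", "H", "E")
  m
}

#' Read a binding annotation table
#'
#' Plain TSV, one protein per line: `protein_id <tab> i1,i2,...` with 1-based
#' binding residue indices (empty second field means no binding residues).
#'
#' @param path annotation file path.
#' @return named list of integer vectors.
#' @export
read_binding_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    tok <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 1L || !nzchar(tok[1])) {
      abort_validation(sprintf("malformed annotation at line %d", ln))
    }
    idx <- if (length(tok) < 2L || !nzchar(trimws(tok[2]))) integer(0) else {
      v <- suppressWarnings(as.integer(strsplit(trimws(tok[2]), ",", fixed = TRUE)[[1]]))
      if (anyNA(v)) abort_validation(sprintf("non-integer binding index at line %d", ln))
      v
    }
    out[[tok[1]]] <- idx
  }
  out
}

#' Logistic normalisation
#'
#' Elementwise `1 / (1 + exp(-x))`, computed in an overflow-safe two-branch
#' form. Maps raw PSSM log-odds into `(0, 1)`.
#'
#' @param m numeric vector or matrix.
#' @return object of the same shape with values in `(0, 1)`.
#' @export
logistic_normalize <- function(m) {
  out <- m
  pos <- m >= 0
  out[pos] <- 1 / (1 + exp(-m[pos]))
  e <- exp(m[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Sliding-window feature vector for one residue
#'
#' Concatenates the `w` rows of `m` centred on residue `i`, in sequence
#' order. Window positions falling outside `[1, L]` contribute all-zero rows
#' (terminal zero-padding; in logistic-normalised space 0 is outside the
#' attainable range `(0,1)`, so padding is distinguishable from signal).
#'
#' @param m L x c numeric matrix of per-residue descriptors.
#' @param i 1-based centre residue.
#' @param w odd window length (default 17).
#' @return numeric vector of length `w * c`.
#' @export
window_features <- function(m, i, w = 17L) {
  if (!is_count(w, 1L) || w %% 2L == 0L) abort_validation("window length must be odd")
  m <- as_feature_matrix(m, "m")
  L <- nrow(m)
  if (!is_count(i, 1L) || i > L) abort_validation("residue index out of range")
  h <- (w - 1L) %/% 2L
  out <- matrix(0, w, ncol(m))
  rows <- (i - h):(i + h)
  inside <- rows >= 1L & rows <= L
  out[inside, ] <- m[rows[inside], , drop = FALSE]
  as.numeric(t(out))
}

#' Build per-residue feature vectors for a protein
#'
#' For each residue: the sliding-window view of the logistic-normalised PSSM
#' (`w * 20` values) followed by the sliding-window view of the
#' secondary-structure probabilities (`w * 3` values); `391` dimensions at
#' the default `w = 17` (`340 + 51`). Labels come from the binding mask
#' (`+1` binding).
#'
#' @param profile a [protein_profile()].
#' @param w odd window length.
#' @return list of class `residue_features` with `dataset` (a
#'   [labeled_dataset()]), `protein_id`, and `residue_index`.
#' @export
build_feature_vectors <- function(profile, w = 17L) {
  stopifnot(inherits(profile, "protein_profile"))
  if (!is_count(w, 1L) || w %% 2L == 0L) abort_validation("window length must be odd")
  L <- nrow(profile$pssm)
  norm_pssm <- logistic_normalize(profile$pssm)
  h <- (w - 1L) %/% 2L
  pad <- function(m) rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
  ppssm <- pad(norm_pssm); pss <- pad(profile$ss_probs)
  block <- function(pm, c) {
    out <- matrix(0, L, w * c)
    for (o in 0:(w - 1L)) {
      out[, (o * c + 1L):((o + 1L) * c)] <- pm[(1L + o):(L + o), , drop = FALSE]
    }
    out
  }
  feats <- cbind(block(ppssm, 20L), block(pss, 3L))
  labels <- ifelse(profile$binding_mask, 1, -1)
  structure(list(dataset = labeled_dataset(feats, labels),
                 protein_id = rep(profile$id, L),
                 residue_index = seq_len(L)),
            class = "residue_features")
}

#' Stack per-protein feature sets into one grouped dataset
#'
#' @param profiles list of [protein_profile()] objects.
#' @param w odd window length.
#' @return list with `dataset` (a [labeled_dataset()]), `groups` (protein id
#'   per row) and `residue_index`.
#' @export
profiles_to_dataset <- function(profiles, w = 17L) {
  sets <- lapply(profiles, build_feature_vectors, w = w)
  feats <- do.call(rbind, lapply(sets, function(s) s$dataset$features))
  labels <- unlist(lapply(sets, function(s) s$dataset$labels))
  list(dataset = labeled_dataset(feats, labels),
       groups = unlist(lapply(sets, function(s) s$protein_id)),
       residue_index = unlist(lapply(sets, function(s) s$residue_index)))
}

#' Write a residue feature table with provenance columns
#'
#' TSV with `protein_id` and `residue_index` provenance columns, the feature
#' columns, then the label; readable by [read_labeled_table()], which strips
#' the provenance into `metadata`.
#'
#' @param rf a `residue_features` object, or the list from
#'   [profiles_to_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rf, path) {
  meta <- data.frame(protein_id = rf$protein_id %||% rf$groups,
                     residue_index = rf$residue_index)
  write_labeled_table(rf$dataset, path, metadata = meta)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
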