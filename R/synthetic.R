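#' Generate a severely imbalanced two-class Gaussian dataset
#'
#' Emulates the class-imbalance regime of nucleotide-binding benchmarks
#' (majority:minority ratios around 19-28): minority rows are drawn from
#' `N(mu1, I)`, majority rows from `N(0, I)`, with `||mu1|| = separation`
#' measured in units of the within-class standard deviation. With
#' `squash = TRUE` features are logistic-squashed into `(0, 1)` to mimic
#' normalised-PSSM ranges.
#'
#' @param n_min,n_maj exact class sizes (minority labelled `+1`).
#' @param d feature dimension.
#' @param separation distance between class means in within-class SD units.
#' @param seed RNG seed.
#' @param squash squash features through the logistic function?
#' @return a [labeled_dataset()] with minority rows first.
#' @export
gen_imbalanced <- function(n_min, n_maj, d = 5L, separation = 2, seed = 0L,
                           squash = FALSE) {
  if (!is_count(n_min, 1L) || !is_count(n_maj, 1L)) {
    abort_validation("class sizes must be positive integers")
  }
  if (!is.numeric(separation) || separation < 0) {
    abort_validation("`separation` must be >= 0")
  }
  mu1 <- rep(separation / sqrt(d), d)
  feats <- local_seed(seed, {
    rbind(sweep(matrix(rnorm(n_min * d), n_min, d), 2L, mu1, "+"),
          matrix(rnorm(n_maj * d), n_maj, d))
  })
  if (squash) feats <- logistic_normalize(feats)
  labeled_dataset(feats, c(rep(1, n_min), rep(-1, n_maj)))
}

#' Generate a toy protein profile with a planted binding signal
#'
#' Builds a profile whose PSSM rows are i.i.d. integer-rounded
#' `N(0, 2^2)` scores (matching the integer log-odds of the PSI-BLAST ASCII
#' dialect), with `+shift` added to the rows at each binding residue and its
#' immediate neighbours (positions within 1) before rounding — a local
#' mean-shift that makes binding learnable from windowed features.
#' Secondary-structure rows are drawn from a symmetric Dirichlet
#' (gamma-normalisation) and carry no signal.
#'
#' @param L sequence length.
#' @param binding_idx 1-based binding residue positions.
#' @param shift mean shift added to PSSM rows near binding residues.
#' @param seed RNG seed.
#' @param id protein identifier.
#' @return a [protein_profile()].
#' @export
gen_toy_profile <- function(L, binding_idx = integer(0), shift = 4, seed = 0L,
                            id = sprintf("toy%05d", as.integer(seed))) {
  if (!is_count(L, 1L)) abort_validation("L must be a positive integer")
  binding_idx <- as.integer(binding_idx)
  if (length(binding_idx) && (any(binding_idx < 1L) || any(binding_idx > L))) {
    abort_validation("binding indices must lie in [1, L]")
  }
  local_seed(seed, {
    seqn <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    pssm <- matrix(rnorm(L * 20, 0, 2), L, 20)
    near <- unique(pmin(pmax(rep(binding_idx, each = 3L) + (-1L):1L, 1L), L))
    pssm[near, ] <- pssm[near, , drop = FALSE] + shift
    pssm <- round(pssm)
    g <- matrix(rgamma(L * 3, shape = 2), L, 3)
    ss <- g / rowSums(g)
    protein_profile(id, seqn, pssm, ss, binding_idx)
  })
}

#' Generate a family of toy profiles
#'
#' @param n number of proteins.
#' @param L sequence length of each.
#' @param n_binding binding residues per protein (positions drawn uniformly
#'   without replacement).
#' @param shift planted mean shift; see [gen_toy_profile()].
#' @param seed RNG seed.
#' @return list of [protein_profile()] objects.
#' @export
gen_toy_proteins <- function(n, L = 25L, n_binding = 2L, shift = 4, seed = 0L) {
  if (!is_count(n, 1L)) abort_validation("n must be a positive integer")
  seeds <- as.integer(seed) + seq_len(n)
  bindings <- local_seed(seed, {
    lapply(seq_len(n), function(i) sort(sample.int(L, n_binding)))
  })
  lapply(seq_len(n), function(i) {
    gen_toy_profile(L, bindings[[i]], shift, seed = seeds[i],
                    id = sprintf("toy%05d", i))
  })
}

#' Write on-disk fixtures for a protein profile
#'
#' Emits the four input files the feature pipeline parses: a FASTA file, a
#' PSI-BLAST-dialect ASCII PSSM (integer log-odds; the percentage block and
#' trailing statistics are zero-filled), a PSIPRED-dialect `.ss2` file
#' (probabilities printed to 3 decimals), and a binding-annotation TSV.
#' Parsing the fixtures back recovers the profile up to format precision
#' (PSSM exactly, since toy PSSMs are integer; ss2 within 1e-3).
#'
#' @param profile a [protein_profile()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths (`fasta`, `pssm`, `ss2`, `annot`).
#' @export
write_fixtures <- function(profile, dir) {
  stopifnot(inherits(profile, "protein_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(profile$sequence)
  letters <- strsplit(profile$sequence, "")[[1]]
  paths <- c(fasta = file.path(dir, paste0(profile$id, ".fasta")),
             pssm = file.path(dir, paste0(profile$id, ".pssm")),
             ss2 = file.path(dir, paste0(profile$id, ".ss2")),
             annot = file.path(dir, paste0(profile$id, "_annot.tsv")))
  writeLines(c(paste0(">", profile$id),
               substring(profile$sequence, seq(1, L, 60), pmin(seq(60, L + 59, 60), L))),
             paths[["fasta"]])
  header <- c("",
              "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
              paste0("            ", paste(sprintf("%3s", AA20), collapse = " "), "  ",
                     paste(sprintf("%3s", AA20), collapse = " ")))
  rows <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s ", i, letters[i]),
           paste(sprintf("%3d", as.integer(round(profile$pssm[i, ]))), collapse = " "),
           "  ", paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(header, rows, ""), paths[["pssm"]])
  state <- c("C", "H", "E")[max.col(profile$ss_probs)]
  ss_rows <- vapply(seq_len(L), function(i) {
    sprintf("%4d %s %s  %5.3f %5.3f %5.3f", i, letters[i], state[i],
            profile$ss_probs[i, 1], profile$ss_probs[i, 2], profile$ss_probs[i, 3])
  }, character(1))
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V3.3)", "", ss_rows), paths[["ss2"]])
  idx <- which(profile$binding_mask)
  writeLines(paste0(profile$id, "\t", paste(idx, collapse = ",")), paths[["annot"]])
  paths
}

#' Read fixtures written by [write_fixtures()] back into a profile
#'
#' @param fasta,pssm,ss2,annot the four file paths.
#' @return a [protein_profile()].
#' @export
read_profile <- function(fasta, pssm, ss2, annot = NULL) {
  fa <- read_fasta(fasta)
  m <- parse_pssm(pssm, sequence = fa$sequence)
  ss <- parse_ss2(ss2)
  binding <- integer(0)
  if (!is.null(annot)) {
    ann <- read_binding_annotation(annot)
    if (!is.null(ann[[fa$id]])) binding <- ann[[fa$id]]
  }
  protein_profile(fa$id, fa$sequence, m, ss, binding)
}
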