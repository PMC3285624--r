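#' Score a single 9-mer window against a PSSM
#'
#' The window score is the sum over pockets P1..P9 of the PSSM entry for the
#' residue seated in that pocket.  Residues outside the 20-letter alphabet
#' (e.g. `X` in crystallographic peptides) contribute 0 to their pocket.
#'
#' @param pssm A [pssm()].
#' @param nonamer 9-character peptide string.
#' @return Numeric score.
#' @export
score_window <- function(pssm, nonamer) {
  stopifnot(inherits(pssm, "pssm"))
  if (nchar(nonamer) != 9L)
    stop("window must be exactly 9 residues, got ", nchar(nonamer))
  ch <- strsplit(nonamer, "", fixed = TRUE)[[1L]]
  known <- ch %in% AA_ALPHABET
  sum(unclass(pssm)[cbind(ch[known], POCKET_IDS[known])])
}

#' Scan a peptide and locate its binding core
#'
#' Scores every 9-mer window of the peptide; the predicted binding core is
#' the maximal-scoring window, ties broken toward the smallest offset
#' (leftmost).
#'
#' @param pssm A [pssm()].
#' @param peptide Peptide string, length >= 9.
#' @return List of class `scan_result`: `peptide`, `window_scores` (one per
#'   offset), `score` (best), `core_start` (0-based offset of the best
#'   window), `core` (the 9-mer).
#' @export
scan_peptide <- function(pssm, peptide) {
  n <- nchar(peptide)
  if (n < 9L)
    stop("peptide '", peptide, "' is shorter than 9 residues")
  offs <- 0:(n - 9L)
  scores <- vapply(offs, function(o)
    score_window(pssm, substr(peptide, o + 1L, o + 9L)), numeric(1L))
  best <- which.max(scores)  # which.max returns the first maximum: leftmost
  structure(list(peptide = peptide,
                 window_scores = scores,
                 score = scores[[best]],
                 core_start = offs[[best]],
                 core = substr(peptide, offs[[best]] + 1L, offs[[best]] + 9L)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("%s  score=%.4f  core=%s  core_start=%d\n",
              x$peptide, x$score, x$core, x$core_start))
  invisible(x)
}

#' Scan many peptides
#'
#' @param pssm A [pssm()].
#' @param peptides Character vector of peptides.
#' @param skip_short If `TRUE` (default) peptides shorter than 9 residues are
#'   dropped with a warning and flagged in the output; otherwise they are an
#'   error.
#' @return data.frame with columns `peptide`, `score`, `core_start`, `core`;
#'   rows in input order.  Attribute `"n_skipped"` counts skipped peptides.
#' @export
scan_peptides <- function(pssm, peptides, skip_short = TRUE) {
  short <- nchar(peptides) < 9L
  if (any(short) && !skip_short)
    stop(sum(short), " peptide(s) shorter than 9 residues")
  if (any(short))
    warning(sum(short), " peptide(s) shorter than 9 residues were skipped")
  kept <- peptides[!short]
  res <- lapply(kept, function(p) scan_peptide(pssm, p))
  out <- data.frame(peptide = kept,
                    score = vapply(res, `[[`, numeric(1L), "score"),
                    core_start = vapply(res, `[[`, integer(1L), "core_start"),
                    core = vapply(res, `[[`, character(1L), "core"))
  attr(out, "n_skipped") <- sum(short)
  out
}

#' Read peptides from FASTA or a plain one-per-line file
#'
#' Files whose first non-blank character is `>` are parsed as FASTA;
#' otherwise each non-blank line is one peptide.
#'
#' @param path Input path.
#' @return Character vector of peptides.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("no peptides found in '", path, "'")
  if (startsWith(trimws(nonblank[[1L]]), ">"))
    as.character(Biostrings::readAAStringSet(path))
  else
    toupper(trimws(nonblank))
}

#' Sample a binding-motif frequency matrix from a PSSM
#'
#' Emulates logo construction by rejection from a random peptide pool:
#' generate `n_peptides` random peptides, score each with the PSSM, keep the
#' top `top_fraction` by score, align each kept peptide at its predicted
#' binding core, and tally per-pocket residue frequencies.  The background
#' amino-acid distribution is uniform by default; empirical frequencies (e.g.
#' proteome composition) can be supplied instead.
#'
#' @param pssm A [pssm()].
#' @param n_peptides Pool size (default 100000).
#' @param top_fraction Fraction kept (default 0.01, i.e. the top 1 percent).
#' @param length Peptide length (default 9, so the core is the peptide).
#' @param background Either `"uniform"` or a named numeric vector of
#'   frequencies over `AA_ALPHABET` (normalized internally).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `motif_matrix`: a 9 x 20 matrix of relative
#'   frequencies (rows = pockets, each summing to 1) with attributes
#'   `n_generated` and `n_selected`.
#' @export
sample_motif <- function(pssm, n_peptides = 100000L, top_fraction = 0.01,
                         length = 9L, background = "uniform", seed = NULL) {
  stopifnot(inherits(pssm, "pssm"))
  if (n_peptides < 100L) stop("n_peptides must be at least 100")
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must be in (0, 1]")
  if (length < 9L) stop("peptide length must be at least 9")
  if (identical(background, "uniform")) {
    prob <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  } else {
    if (is.null(names(background)) || !all(names(background) %in% AA_ALPHABET))
      stop("background must be 'uniform' or frequencies named by amino acid")
    prob <- stats::setNames(rep(0, 20L), AA_ALPHABET)
    prob[names(background)] <- background
    if (any(prob < 0) || sum(prob) <= 0) stop("invalid background frequencies")
    prob <- prob / sum(prob)
  }
  if (sum(prob > 0) < 2L)
    stop("degenerate background: fewer than two residues have mass")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chars <- sample(AA_ALPHABET, n_peptides * length, replace = TRUE, prob = prob)
  pep <- matrix(chars, nrow = n_peptides)
  # score all windows vectorized over the pool
  n_win <- length - 8L
  scores <- matrix(0, n_peptides, n_win)
  vals <- unclass(pssm)
  for (o in seq_len(n_win)) {
    for (p in 1:9)
      scores[, o] <- scores[, o] + vals[cbind(pep[, o + p - 1L], POCKET_IDS[p])]
  }
  best_off <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(n_peptides), best_off)]
  n_sel <- ceiling(top_fraction * n_peptides)
  sel <- order(best, decreasing = TRUE)[seq_len(n_sel)]
  freq <- matrix(0, 9L, 20L, dimnames = list(POCKET_IDS, AA_ALPHABET))
  for (p in 1:9) {
    res <- pep[cbind(sel, best_off[sel] + p - 1L)]
    tab <- table(factor(res, levels = AA_ALPHABET))
    freq[p, ] <- as.numeric(tab) / n_sel
  }
  structure(freq, n_generated = n_peptides, n_selected = n_sel,
            class = c("motif_matrix", "matrix"))
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("Binding-motif frequency matrix (", attr(x, "n_selected"), " of ",
      attr(x, "n_generated"), " peptides)\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Write a motif matrix as TSV (pocket x amino acid)
#' @param x A `motif_matrix`.
#' @param path Output path.
#' @export
write_motif_matrix <- function(x, path) {
  stopifnot(inherits(x, "motif_matrix"))
  df <- as.data.frame(unclass(x))
  utils::write.table(cbind(pocket = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
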