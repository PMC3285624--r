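#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — computed from rank
#' sums, so it is exact and O(n log n).
#'
#' @param scores Numeric prediction scores (higher = more binder-like).
#' @param labels Binary labels (1/TRUE = binder).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires both classes; got ", n_pos, " positives and ",
         n_neg, " negatives")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Label benchmark records by an affinity threshold
#'
#' A peptide is a binder iff its measured affinity is at or below the
#' threshold (boundary inclusive; stronger binding = lower nM).  The
#' threshold may be a single value or per-allele: classical benchmarking uses
#' 100 nM for some alleles and 1000 nM for the rest.
#'
#' @param records data.frame with columns `allele`, `peptide`,
#'   `affinity_nM` (and optionally others).
#' @param threshold_nM Single numeric threshold, or a named numeric vector
#'   keyed by allele (a `default` entry covers unlisted alleles).
#' @return The records with a logical `label` column added.
#' @export
threshold_labels <- function(records, threshold_nM = 1000) {
  if (!"affinity_nM" %in% names(records) || anyNA(records$affinity_nM))
    stop("records lack affinity_nM values")
  if (any(records$affinity_nM <= 0)) stop("affinities must be positive")
  if (length(threshold_nM) == 1L && is.null(names(threshold_nM))) {
    thr <- rep(threshold_nM, nrow(records))
  } else {
    thr <- threshold_nM[records$allele]
    miss <- is.na(thr)
    if (any(miss)) {
      if (!"default" %in% names(threshold_nM))
        stop("no threshold for allele(s): ",
             paste(unique(records$allele[miss]), collapse = ", "))
      thr[miss] <- threshold_nM[["default"]]
    }
  }
  records$label <- records$affinity_nM <= thr
  records
}

#' One-tailed exact binomial test for paired method comparison
#'
#' Given per-allele win/loss counts of method A against method B (ties
#' excluded before calling), returns the exact one-tailed probability of at
#' least this many wins under the null that either method wins each
#' comparison with probability one half: `P(X >= wins)` for
#' `X ~ Binomial(wins + losses, 0.5)`.
#'
#' @param wins,losses Non-negative integer counts; `wins + losses >= 1`.
#' @return Exact p-value.
#' @examples
#' per_allele_binomial(9, 1)   # 11/1024
#' @export
per_allele_binomial <- function(wins, losses) {
  stopifnot(wins >= 0, losses >= 0)
  n <- wins + losses
  if (n == 0L)
    stop("all comparisons are ties; the test is undefined")
  stats::pbinom(wins - 1, size = n, prob = 0.5, lower.tail = FALSE)
}

#' Count exact-core prediction errors
#'
#' A prediction is an error unless its predicted 0-based core offset equals
#' the true offset exactly: a near-miss shifted by one position is still an
#' error.
#'
#' @param results data.frame from [scan_peptides()] (columns `peptide`,
#'   `core_start`, ...), one row per truth record, same order.
#' @param truth data.frame with columns `peptide` and `core_start` (true
#'   0-based offset); an optional `id` column is carried through.
#' @return List with `n_errors` and `report` (per-record data.frame with
#'   `predicted`, `truth`, `error`).
#' @export
core_error_count <- function(results, truth) {
  if (nrow(results) != nrow(truth))
    stop("results and truth differ in length")
  if (!all(results$peptide == truth$peptide))
    stop("peptide mismatch between results and truth at row ",
         which(results$peptide != truth$peptide)[[1L]])
  report <- data.frame(
    id = if ("id" %in% names(truth)) truth$id else seq_len(nrow(truth)),
    peptide = truth$peptide,
    predicted = results$core_start,
    truth = truth$core_start,
    error = results$core_start != truth$core_start)
  list(n_errors = sum(report$error), report = report)
}

#' Per-allele benchmark evaluation
#'
#' Scores every benchmark peptide with the PSSM synthesized (or supplied) for
#' its allele and reports one row per allele: peptide count, binder count and
#' AUC (NA when an allele has a single class).
#'
#' @param records Labeled benchmark data.frame (`allele`, `peptide`, `label`;
#'   see [threshold_labels()]).
#' @param pssms Named list of [pssm()] objects keyed by allele, covering every
#'   allele present.
#' @return data.frame with columns `allele`, `count`, `binder`, `auc`.
#' @export
evaluate_benchmark <- function(records, pssms) {
  need <- setdiff(unique(records$allele), names(pssms))
  if (length(need))
    stop("no PSSM for allele(s): ", paste(need, collapse = ", "))
  rows <- lapply(unique(records$allele), function(a) {
    sub <- records[records$allele == a, ]
    sc <- scan_peptides(pssms[[a]], sub$peptide, skip_short = FALSE)$score
    aval <- if (length(unique(sub$label)) < 2L) NA_real_ else auc(sc, sub$label)
    data.frame(allele = a, count = nrow(sub), binder = sum(sub$label),
               auc = aval)
  })
  do.call(rbind, rows)
}

#' Sweep the weighting exponent alpha on a benchmark
#'
#' Re-synthesizes each allele's PSSM at every alpha in the grid (plus the
#' 1-KNN rule, `alpha = Inf`) and reports the per-allele and mean AUC, the
#' shape study used to select the default alpha = 9.
#'
#' @param records Labeled benchmark records.
#' @param library A [matrix_library()].
#' @param library_pseqs Pseudosequences of the library alleles.
#' @param query_pseqs Named list: benchmark allele -> its 9 pseudosequences.
#' @param alphas Numeric grid (may include `Inf` for 1-KNN); default mirrors
#'   the published grid 1..50 plus 1-KNN.
#' @return data.frame with columns `alpha`, `allele`, `auc`.
#' @export
alpha_sweep <- function(records, library, library_pseqs, query_pseqs,
                        alphas = c(1, 3, 5, 9, 10, 20, 30, 50, Inf)) {
  rows <- lapply(alphas, function(a) {
    pssms <- lapply(query_pseqs, function(ps)
      synthesize_pssm(ps, library, library_pseqs, alpha = a))
    ev <- evaluate_benchmark(records, pssms)
    cbind(alpha = a, ev[, c("allele", "auc")])
  })
  do.call(rbind, rows)
}

#' Read / write benchmark tables
#'
#' TSV with header; columns `allele`, `peptide`, then either `affinity_nM`
#' or `label` (0/1).
#'
#' @param path File path.
#' @param records Benchmark data.frame.
#' @return `read_benchmark()` returns the data.frame with alleles normalized.
#' @export
read_benchmark <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "peptide") %in% names(df)))
    stop("benchmark must have columns allele, peptide")
  if (!("affinity_nM" %in% names(df) || "label" %in% names(df)))
    stop("benchmark must have an affinity_nM or label column")
  df$allele <- normalize_allele_name(df$allele)
  if ("label" %in% names(df)) df$label <- as.logical(df$label)
  df
}

#' @rdname read_benchmark
#' @export
write_benchmark <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
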