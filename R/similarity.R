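#' Raw BLOSUM pocket similarity
#'
#' The raw similarity between two pocket pseudosequences of equal length is
#' the sum over positions of the substitution-matrix score of the paired
#' residues.
#'
#' @param query_pseq,lib_pseq Pseudosequences (equal-length residue strings
#'   over the 20-letter alphabet).
#' @param matrix 20 x 20 substitution matrix; default BLOSUM62.
#' @return Integer score.
#' @examples
#' raw_similarity("AAAA", "AAAA")  # 16
#' raw_similarity("W", "W")        # 11
#' @export
raw_similarity <- function(query_pseq, lib_pseq,
                           matrix = default_substitution_matrix()) {
  q <- check_residues(query_pseq, "query pseudosequence")
  l <- check_residues(lib_pseq, "library pseudosequence")
  if (length(q) != length(l))
    stop("pseudosequence length mismatch: ", length(q), " vs ", length(l))
  sum(matrix[cbind(q, l)])
}

#' Normalized pocket similarity
#'
#' Rescales the per-position BLOSUM score so the result lies in \[0, 1\]:
#' for a query residue `q_i`, position `i` contributes
#' `(B(q_i, l_i) - m_i) / (M_i - m_i)` where `M_i = B(q_i, q_i)` (the maximal
#' attainable score, since the BLOSUM62 diagonal dominates its row) and
#' `m_i = min_b B(q_i, b)`; the similarity is the mean contribution over the
#' pocket's positions.  It equals 1 exactly when the partner matches the
#' query's self-score at every position (in particular for identical
#' pseudosequences) and 0 exactly when every position attains the row
#' minimum.  The measure is asymmetric: the first argument always plays the
#' role of the query.
#'
#' @inheritParams raw_similarity
#' @return Numeric in \[0, 1\].
#' @examples
#' normalized_similarity("WNF", "WNF")  # 1
#' @export
normalized_similarity <- function(query_pseq, lib_pseq,
                                  matrix = default_substitution_matrix()) {
  q <- check_residues(query_pseq, "query pseudosequence")
  l <- check_residues(lib_pseq, "library pseudosequence")
  if (length(q) != length(l))
    stop("pseudosequence length mismatch: ", length(q), " vs ", length(l))
  M <- matrix[cbind(q, q)]
  m <- apply(matrix[q, , drop = FALSE], 1L, min)
  b <- matrix[cbind(q, l)]
  mean((b - m) / (M - m))
}

#' Per-pocket library weights for a query allele
#'
#' For every pocket, each library allele receives weight proportional to its
#' normalized pocket similarity raised to the exponent `alpha`:
#' `w_p(q, l) = S_p(q, l)^alpha / sum_l' S_p(q, l')^alpha`.  A larger `alpha`
#' concentrates weight on the most similar alleles; as `alpha -> Inf` the
#' weights converge to the 1-KNN rule (all weight on the allele(s) of maximal
#' similarity, ties sharing equally), which is also available directly via
#' `alpha = Inf`.
#'
#' @param query_pseqs Named character vector of the query's 9 pocket
#'   pseudosequences (as from [extract_pseudosequences()]).
#' @param library_pseqs Named list: allele -> named character vector of that
#'   allele's 9 pocket pseudosequences.
#' @param alpha Positive weighting exponent (default 9), or `Inf` for 1-KNN.
#' @param matrix Substitution matrix.
#' @return A data.frame of class `similarity_profile` with columns `pocket`,
#'   `allele`, `raw`, `similarity`, `weight`; within each pocket the weights
#'   sum to 1.
#' @export
pocket_weights <- function(query_pseqs, library_pseqs,
                           alpha = 9,
                           matrix = default_substitution_matrix()) {
  if (length(library_pseqs) == 0L)
    stop("library is empty")
  if (is.null(names(library_pseqs)))
    stop("library pseudosequences must be named by allele")
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0))
    stop("alpha must be a positive number")
  alleles <- names(library_pseqs)
  rows <- lapply(POCKET_IDS, function(p) {
    raw <- vapply(alleles, function(a)
      raw_similarity(query_pseqs[[p]], library_pseqs[[a]][[p]], matrix),
      numeric(1L))
    S <- vapply(alleles, function(a)
      normalized_similarity(query_pseqs[[p]], library_pseqs[[a]][[p]], matrix),
      numeric(1L))
    if (all(S == 0))
      stop("all library similarities are zero for pocket ", p,
           "; cannot form weights")
    if (is.infinite(alpha)) {
      w <- as.numeric(S == max(S))
    } else {
      w <- S^alpha
    }
    w <- w / sum(w)
    data.frame(pocket = p, allele = alleles, raw = raw,
               similarity = S, weight = w, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_profile", "data.frame")
  out
}
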