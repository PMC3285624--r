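#' Pocket specificity matrices (PSSMs) and matrix libraries
#'
#' A PSSM is a 20 x 9 numeric matrix: rows are amino acids in [AA_ALPHABET]
#' order, columns are pockets P1..P9.  Column `p` is the binding specificity
#' vector of pocket `p`; pockets in the library's unused mask carry all-zero
#' columns.  A matrix library is a named collection of PSSMs sharing one
#' unused-pocket mask.
#'
#' @param values 20 x 9 numeric matrix (rows may be named by amino acid,
#'   columns by pocket; unnamed input is taken in `AA_ALPHABET` x
#'   `POCKET_IDS` order).
#' @param allele Allele name (normalized on construction).
#' @param mask Character vector of unused pockets whose columns must be zero;
#'   columns listed here are zeroed.
#' @return `pssm()` returns an object of class `pssm`.
#' @export
pssm <- function(values, allele = "<query>", mask = DEFAULT_UNUSED_POCKETS) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(20L, 9L)))
    stop("a PSSM must be 20 x 9, got ", nrow(values), " x ", ncol(values))
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("PSSM values must be finite numbers")
  if (!is.null(rownames(values))) {
    if (!setequal(rownames(values), AA_ALPHABET))
      stop("PSSM row names must be the 20 amino acids")
    values <- values[AA_ALPHABET, , drop = FALSE]
  } else rownames(values) <- AA_ALPHABET
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), POCKET_IDS))
      stop("PSSM column names must be P1..P9")
    values <- values[, POCKET_IDS, drop = FALSE]
  } else colnames(values) <- POCKET_IDS
  mask <- as.character(mask)
  if (!all(mask %in% POCKET_IDS))
    stop("mask entries must be pocket ids")
  values[, mask] <- 0
  structure(values, allele = allele, mask = mask, class = c("pssm", "matrix"))
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for allele ", attr(x, "allele"), "\n", sep = "")
  if (length(attr(x, "mask")))
    cat("unused pockets:", paste(attr(x, "mask"), collapse = " "), "\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Construct a matrix library
#'
#' @param pssms Named list of [pssm()] objects (or bare 20 x 9 matrices),
#'   names = allele names, normalized and required unique.
#' @param mask Unused-pocket mask applied to every matrix.
#' @return Object of class `matrix_library`: list with elements `pssms`
#'   (named list of `pssm`) and `mask`.
#' @export
matrix_library <- function(pssms, mask = DEFAULT_UNUSED_POCKETS) {
  if (length(pssms) == 0L) stop("library must contain at least one PSSM")
  if (is.null(names(pssms))) stop("PSSMs must be named by allele")
  alleles <- normalize_allele_name(names(pssms))
  if (anyDuplicated(alleles))
    stop("duplicate allele in library: ", alleles[duplicated(alleles)][[1L]])
  pssms <- lapply(seq_along(pssms), function(i)
    pssm(unclass(pssms[[i]]), allele = alleles[[i]], mask = mask))
  names(pssms) <- alleles
  structure(list(pssms = pssms, mask = as.character(mask)),
            class = "matrix_library")
}

#' @export
print.matrix_library <- function(x, ...) {
  cat("Matrix library: ", length(x$pssms), " PSSM(s); unused pockets: ",
      if (length(x$mask)) paste(x$mask, collapse = " ") else "<none>",
      "\n  alleles: ", paste(names(x$pssms), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write matrix libraries as TSV
#'
#' Format: a header line `allele<TAB>pocket<TAB>A<TAB>C...<TAB>Y` giving the
#' amino-acid column order, then one line per (allele, pocket):
#' `allele<TAB>pocket<TAB>20 tab-separated reals`.  Pockets in the unused
#' mask may be omitted and are filled with zeros on load.
#'
#' @param path File path.
#' @param library A `matrix_library`.
#' @param mask Unused-pocket mask to apply on load (default `{P5, P8}`);
#'   omitted pockets outside the mask are an error.
#' @return `read_matrix_library()` returns a `matrix_library`;
#'   `write_matrix_library()` returns `path` invisibly.
#' @export
read_matrix_library <- function(path, mask = DEFAULT_UNUSED_POCKETS) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) < 2L) stop("matrix library '", path, "' is empty")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 22L || !setequal(header[-(1:2)], AA_ALPHABET))
    stop("line 1: header must be allele, pocket, then the 20 amino acids")
  aa_order <- header[-(1:2)]
  acc <- list()
  for (i in seq_along(lines)[-1L]) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 22L)
      stop("line ", i, ": expected 22 fields, got ", length(f))
    allele <- f[[1L]]; pocket <- f[[2L]]
    if (!pocket %in% POCKET_IDS)
      stop("line ", i, ": unknown pocket '", pocket, "'")
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v))
      stop("line ", i, ": malformed number in pocket ", pocket,
           " of allele ", allele)
    if (is.null(acc[[allele]]))
      acc[[allele]] <- matrix(NA_real_, 20L, 9L,
                              dimnames = list(AA_ALPHABET, POCKET_IDS))
    if (!all(is.na(acc[[allele]][, pocket])))
      stop("line ", i, ": duplicate pocket ", pocket, " for allele ", allele)
    acc[[allele]][aa_order, pocket] <- v
  }
  pssms <- lapply(names(acc), function(a) {
    m <- acc[[a]]
    missing <- POCKET_IDS[apply(m, 2L, function(col) all(is.na(col)))]
    extra <- setdiff(missing, mask)
    if (length(extra))
      stop("allele ", a, ": missing pocket column(s) ",
           paste(extra, collapse = ", "))
    m[, missing] <- 0
    m
  })
  names(pssms) <- names(acc)
  matrix_library(pssms, mask = mask)
}

#' @rdname read_matrix_library
#' @export
write_matrix_library <- function(library, path) {
  stopifnot(inherits(library, "matrix_library"))
  lines <- c(paste(c("allele", "pocket", AA_ALPHABET), collapse = "\t"))
  for (a in names(library$pssms)) {
    m <- library$pssms[[a]]
    for (p in setdiff(POCKET_IDS, library$mask))
      lines <- c(lines, paste(c(a, p, format(m[, p], trim = TRUE, digits = 15)),
                              collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write one PSSM as a plain 9 x 20 TSV (pockets as rows)
#'
#' Interoperable with sequence-logo tools that expect a position x residue
#' table.
#'
#' @param x A `pssm`.
#' @param path Output path.
#' @export
write_pssm_tsv <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  df <- as.data.frame(t(unclass(x)))
  utils::write.table(cbind(pocket = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthesize the PSSM of a query allele from a matrix library
#'
#' For every pocket not in the library's unused mask, the query's specificity
#' vector is the weighted average of the library alleles' vectors for that
#' pocket, with per-pocket weights from [pocket_weights()].  Unused pockets
#' get zero vectors.
#'
#' @param query_pseqs The query allele's 9 pocket pseudosequences (named
#'   character vector, as from [extract_pseudosequences()]).
#' @param library A [matrix_library()].
#' @param library_pseqs Named list: library allele -> its 9 pseudosequences.
#'   Must cover every library allele.
#' @param alpha Weighting exponent (default 9); `Inf` gives the 1-KNN rule.
#' @param matrix Substitution matrix.
#' @param allele Name recorded on the returned PSSM.
#' @return A `pssm`, with the `similarity_profile` used attached as
#'   attribute `"profile"`.
#' @export
synthesize_pssm <- function(query_pseqs, library, library_pseqs,
                            alpha = 9,
                            matrix = default_substitution_matrix(),
                            allele = "<query>") {
  stopifnot(inherits(library, "matrix_library"))
  missing <- setdiff(names(library$pssms), names(library_pseqs))
  if (length(missing))
    stop("no pseudosequences for library allele(s): ",
         paste(missing, collapse = ", "))
  prof <- pocket_weights(query_pseqs, library_pseqs[names(library$pssms)],
                         alpha = alpha, matrix = matrix)
  out <- matrix(0, 20L, 9L, dimnames = list(AA_ALPHABET, POCKET_IDS))
  for (p in setdiff(POCKET_IDS, library$mask)) {
    w <- prof[prof$pocket == p, ]
    vecs <- vapply(w$allele, function(a) library$pssms[[a]][, p], numeric(20L))
    out[, p] <- as.numeric(vecs %*% w$weight)
  }
  res <- pssm(out, allele = allele, mask = library$mask)
  attr(res, "profile") <- prof
  res
}

#' Count distinct pocket specificity vectors in a library
#'
#' Reports how many distinct (exact value equality) specificity vectors the
#' library contains across all alleles and non-masked pockets, and which
#' (allele, pocket) pairs share each vector.  The classical 11-allele HLA-DR
#' library holds 35 distinct vectors rather than 9 x 11 = 99, because two
#' pockets are unused and several alleles share pocket specificities.
#'
#' @param library A `matrix_library`.
#' @return List with `n_unique` (integer) and `groups` (list of character
#'   vectors `"allele/pocket"`, one per distinct vector).
#' @export
count_unique_vectors <- function(library) {
  stopifnot(inherits(library, "matrix_library"))
  keys <- character(0); members <- character(0)
  for (a in names(library$pssms)) {
    m <- library$pssms[[a]]
    for (p in setdiff(POCKET_IDS, library$mask)) {
      keys <- c(keys, paste(format(m[, p], digits = 17), collapse = ","))
      members <- c(members, paste0(a, "/", p))
    }
  }
  groups <- split(members, factor(keys, levels = unique(keys)))
  names(groups) <- NULL
  list(n_unique = length(groups), groups = groups)
}
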