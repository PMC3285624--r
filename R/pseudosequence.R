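#' Normalize an HLA-DRB allele name to current nomenclature
#'
#' Accepts current colon-delimited names (`DRB1*01:01`), legacy digit-run
#' names (`DRB1*0101`, `DRB1_0101`), and an optional `HLA-` prefix, and
#' returns the colon-delimited form.  Field suffixes beyond the first two
#' (e.g. `DRB1*01:01:01` or a legacy six-digit run) are preserved as extra
#' colon-separated fields.  The function is idempotent.
#'
#' @param raw Allele name string(s).
#' @return Character vector of normalized names, e.g. `"DRB1*01:01"`.
#' @examples
#' normalize_allele_name("DRB1*0101")     # "DRB1*01:01"
#' normalize_allele_name("HLA-DRB5*01:01") # "DRB5*01:01"
#' @export
normalize_allele_name <- function(raw) {
  vapply(raw, function(x) {
    if (!is.character(x) || is.na(x) || !nzchar(trimws(x)))
      stop("allele name is empty")
    s <- toupper(trimws(x))
    s <- sub("^HLA-", "", s)
    s <- gsub("_", "*", s, fixed = TRUE)
    m <- regexec("^(DRB[0-9])\\*([0-9:]+)$", s)
    parts <- regmatches(s, m)[[1L]]
    if (length(parts) != 3L)
      stop("cannot parse allele name: '", x, "'")
    locus <- parts[[2L]]
    fields <- parts[[3L]]
    if (grepl(":", fields, fixed = TRUE)) {
      segs <- strsplit(fields, ":", fixed = TRUE)[[1L]]
      if (any(!nzchar(segs)) || any(nchar(segs) < 2L))
        stop("cannot parse allele fields in: '", x, "'")
    } else {
      if (nchar(fields) < 4L || nchar(fields) %% 2L != 0L)
        stop("cannot parse legacy allele digits in: '", x, "'")
      segs <- substring(fields,
                        seq(1L, nchar(fields) - 1L, by = 2L),
                        seq(2L, nchar(fields), by = 2L))
    }
    paste0(locus, "*", paste(segs, collapse = ":"))
  }, character(1L), USE.NAMES = FALSE)
}

#' Read aligned DRB beta1-domain sequences from FASTA
#'
#' The FASTA header (first whitespace-delimited token) is the allele name and
#' is normalized on load.  Sequences must already be aligned to mature-protein
#' numbering: character `k` of the sequence is residue position `k`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = normalized alleles).
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    stop("no sequences found in '", path, "'")
  nm <- normalize_allele_name(vapply(strsplit(names(seqs), "\\s+"),
                                     `[[`, character(1L), 1L))
  if (anyDuplicated(nm))
    stop("duplicate allele in '", path, "': ",
         nm[duplicated(nm)][[1L]])
  stats::setNames(as.character(seqs), nm)
}

#' Extract per-pocket pseudosequences from an aligned DRB sequence
#'
#' A pocket's pseudosequence is the string of residues found at that pocket's
#' contact positions, in table order.  A gap, `X`, or any character outside
#' the 20-letter alphabet at a required position is an error, not silently
#' skipped.
#'
#' @param sequence Aligned beta1-domain amino-acid string (position `k` =
#'   character `k`), or a named length-1 character vector (name = allele,
#'   used in error messages).
#' @param table A [pocket_table()]; default [default_pocket_table()].
#' @param allele Optional allele name for error messages.
#' @return Named character vector of 9 pseudosequences (names = pocket ids).
#' @examples
#' seq <- paste(rep("A", 90), collapse = "")
#' extract_pseudosequences(seq)[["P1"]]  # "AAAA"
#' @export
extract_pseudosequences <- function(sequence, table = default_pocket_table(),
                                    allele = NULL) {
  if (is.null(allele) && !is.null(names(sequence)))
    allele <- names(sequence)[[1L]]
  if (is.null(allele)) allele <- "<query>"
  sequence <- unname(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  maxpos <- max(unlist(table))
  if (nchar(sequence) < maxpos)
    stop("sequence of allele ", allele, " (length ", nchar(sequence),
         ") does not cover position ", maxpos)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- vapply(POCKET_IDS, function(p) {
    res <- chars[table[[p]]]
    bad <- which(!(res %in% AA_ALPHABET))
    if (length(bad))
      stop("allele ", allele, ", pocket ", p, ", position ",
           table[[p]][bad[[1L]]], ": invalid residue '", res[bad[[1L]]], "'")
    paste(res, collapse = "")
  }, character(1L))
  out
}
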