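#' Read a substitution matrix in NCBI plain-text layout
#'
#' Parses the standard NCBI matrix format (comment lines starting with `#`,
#' a header row of residue codes, then one labelled row per residue) as used
#' for BLOSUM and PAM matrices.  Ambiguity codes (`B`, `Z`, `X`, `*`) present
#' in the file are read but dropped: the returned matrix is restricted to the
#' 20 standard amino acids in [AA_ALPHABET] order.
#'
#' @param path Path to the matrix file.  Defaults to the BLOSUM62 matrix
#'   bundled with the package.
#' @return Integer matrix, 20 x 20, dimnames = `AA_ALPHABET`, symmetric.
#' @examples
#' b62 <- read_substitution_matrix()
#' b62["A", "A"]  # 4
#' b62["W", "W"]  # 11
#' @export
read_substitution_matrix <- function(path = system.file("extdata", "BLOSUM62.txt",
                                                        package = "drpan")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("substitution matrix file '", path, "' has no data rows")
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[[`, character(1L), 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v) || length(v) != length(header))
      stop("malformed substitution matrix row starting with '", r[[1L]], "'")
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  missing <- setdiff(AA_ALPHABET, labels)
  if (length(missing))
    stop("substitution matrix lacks residues: ", paste(missing, collapse = ", "))
  m <- m[AA_ALPHABET, AA_ALPHABET]
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric")
  m
}

# Cached default matrix; computed lazily once per session.
.b62_cache <- new.env(parent = emptyenv())

default_substitution_matrix <- function() {
  if (is.null(.b62_cache$m))
    .b62_cache$m <- read_substitution_matrix()
  .b62_cache$m
}

# Validate a residue string against the 20-letter alphabet; returns the
# character vector of residues.  `what` names the offending object in errors.
check_residues <- function(x, what = "sequence") {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, AA_ALPHABET)
  if (length(bad))
    stop(what, " contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "))
  ch
}
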