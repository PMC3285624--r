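#' Pocket contact-position table
#'
#' A pocket table maps each of the nine binding pockets P1..P9 to the DRB
#' beta1-domain residue positions (1-based, mature-protein numbering) whose
#' side chains line that pocket.  The default table is the union of contact
#' residues observed across 32 crystallographic HLA-peptide complexes.
#'
#' @param entries Named list: pocket id -> integer vector of positions.
#' @return An object of class `pocket_table` (a named list of integer
#'   vectors with the nine pockets in order).
#' @examples
#' tab <- default_pocket_table()
#' tab$P1  # 82 85 86 89
#' @export
pocket_table <- function(entries) {
  if (!setequal(names(entries), POCKET_IDS))
    stop("pocket table must define exactly the pockets ",
         paste(POCKET_IDS, collapse = ", "))
  entries <- entries[POCKET_IDS]
  for (p in POCKET_IDS) {
    pos <- as.integer(entries[[p]])
    if (length(pos) == 0L)
      stop("pocket ", p, " has no positions")
    if (anyNA(pos) || any(pos < 1L) || any(pos > 120L))
      stop("pocket ", p, " has positions outside 1..120")
    if (is.unsorted(pos, strictly = TRUE))
      stop("pocket ", p, " positions must be strictly increasing")
    entries[[p]] <- pos
  }
  structure(entries, class = "pocket_table")
}

#' @rdname pocket_table
#' @export
default_pocket_table <- function() {
  pocket_table(list(
    P1 = c(82L, 85L, 86L, 89L),
    P2 = c(77L, 78L, 81L, 82L),
    P3 = 78L,
    P4 = c(11L, 13L, 26L, 28L, 70L, 71L, 74L, 78L),
    P5 = c(11L, 13L, 28L, 70L, 71L, 74L),
    P6 = c(11L, 13L, 28L, 30L, 61L, 71L),
    P7 = c(11L, 28L, 30L, 47L, 61L, 67L, 70L, 71L),
    P8 = c(60L, 61L),
    P9 = c(9L, 30L, 37L, 57L, 60L, 61L)
  ))
}

#' @export
print.pocket_table <- function(x, ...) {
  cat("Pocket contact-position table\n")
  for (p in POCKET_IDS)
    cat(sprintf("  %-3s %s\n", p, paste(x[[p]], collapse = " ")))
  invisible(x)
}

#' Read / write a pocket table as TSV
#'
#' One row per pocket: `pocket<TAB>comma-separated positions`.
#'
#' @param path File path.
#' @param table A `pocket_table`.
#' @return `read_pocket_table()` returns a `pocket_table`;
#'   `write_pocket_table()` returns `path` invisibly.
#' @export
read_pocket_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("pocket", "positions"),
                          colClasses = "character", strip.white = TRUE)
  entries <- lapply(df$positions, function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  names(entries) <- df$pocket
  pocket_table(entries)
}

#' @rdname read_pocket_table
#' @export
write_pocket_table <- function(table, path) {
  stopifnot(inherits(table, "pocket_table"))
  lines <- vapply(POCKET_IDS, function(p)
    paste0(p, "\t", paste(table[[p]], collapse = ",")), character(1L))
  writeLines(lines, path)
  invisible(path)
}
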