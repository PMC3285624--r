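#' Read ATOM records from a PDB-format coordinate file
#'
#' Minimal fixed-width parser for the PDB v3 ATOM record: no installed R
#' package in this stack reads PDB, and only chain, residue and coordinate
#' fields are needed here.  HETATM records (waters, ligands) are ignored.
#'
#' @param path PDB file path.
#' @return data.frame with columns `atom` (atom name), `element`, `chain`,
#'   `resseq` (author residue number), `resname`, `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0L) stop("no ATOM records in '", path, "'")
  fw <- function(l, a, b) trimws(substr(l, a, b))
  df <- data.frame(
    atom    = vapply(lines, fw, character(1L), 13L, 16L, USE.NAMES = FALSE),
    element = vapply(lines, fw, character(1L), 77L, 78L, USE.NAMES = FALSE),
    chain   = vapply(lines, fw, character(1L), 22L, 22L, USE.NAMES = FALSE),
    resseq  = as.integer(vapply(lines, fw, character(1L), 23L, 26L, USE.NAMES = FALSE)),
    resname = vapply(lines, fw, character(1L), 18L, 20L, USE.NAMES = FALSE),
    x = as.numeric(vapply(lines, fw, character(1L), 31L, 38L, USE.NAMES = FALSE)),
    y = as.numeric(vapply(lines, fw, character(1L), 39L, 46L, USE.NAMES = FALSE)),
    z = as.numeric(vapply(lines, fw, character(1L), 47L, 54L, USE.NAMES = FALSE))
  )
  if (anyNA(df$resseq) || anyNA(df$x))
    stop("malformed ATOM record in '", path, "'")
  # element column may be blank in older files; fall back to atom-name initial
  blank <- !nzchar(df$element)
  df$element[blank] <- substr(gsub("[0-9]", "", df$atom[blank]), 1L, 1L)
  df
}

#' Derive pocket contact positions from one MHC-peptide complex
#'
#' For each of the nine binding-core residues (core residue `j` sits in
#' pocket `Pj`), an MHC residue is a contact if the minimum inter-atomic
#' distance between any of its atoms and any atom of the core residue is
#' within `cutoff` (inclusive; default 4 angstrom).  Hydrogens are excluded
#' by default; HETATM records never participate.
#'
#' @param atoms data.frame from [read_pdb_atoms()] (or equivalent).
#' @param mhc_chain,peptide_chain Chain identifiers.
#' @param core_resseq Integer vector of 9 residue numbers of the binding core
#'   within the peptide chain, in core order P1..P9.
#' @param cutoff Distance cutoff in angstrom (default 4.0, boundary
#'   inclusive).
#' @param heavy_only Exclude hydrogen atoms from the distance test (default
#'   `TRUE`); set `FALSE` to use all atoms.
#' @param pdb_id Identifier recorded on the result.
#' @param offset Added to MHC author residue numbers to map them onto the
#'   mature-protein alignment numbering (default 0: numbering already
#'   matches).
#' @return data.frame of class `contact_record` with columns `pdb_id`,
#'   `pocket`, `position` (one row per contact; pockets with no contacts
#'   contribute no rows).
#' @export
find_contact_positions <- function(atoms, mhc_chain, peptide_chain,
                                   core_resseq, cutoff = 4.0,
                                   heavy_only = TRUE, pdb_id = "struct",
                                   offset = 0L) {
  stopifnot(length(core_resseq) == 9L, cutoff > 0)
  if (heavy_only) atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  mhc <- atoms[atoms$chain == mhc_chain, , drop = FALSE]
  pep <- atoms[atoms$chain == peptide_chain, , drop = FALSE]
  if (nrow(mhc) == 0L) stop(pdb_id, ": MHC chain '", mhc_chain, "' not found")
  if (nrow(pep) == 0L)
    stop(pdb_id, ": peptide chain '", peptide_chain, "' not found")
  mhc_xyz <- as.matrix(mhc[, c("x", "y", "z")])
  rows <- lapply(1:9, function(j) {
    core <- pep[pep$resseq == core_resseq[[j]], , drop = FALSE]
    if (nrow(core) == 0L)
      stop(pdb_id, ": core residue ", core_resseq[[j]],
           " unresolved in chain ", peptide_chain)
    core_xyz <- as.matrix(core[, c("x", "y", "z")])
    # min distance from every MHC atom to any core atom
    d2 <- outer(rowSums(mhc_xyz^2), rowSums(core_xyz^2), "+") -
      2 * (mhc_xyz %*% t(core_xyz))
    hit <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
    pos <- sort(unique(mhc$resseq[hit])) + offset
    if (length(pos) == 0L) return(NULL)
    data.frame(pdb_id = pdb_id, pocket = POCKET_IDS[[j]], position = pos)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pdb_id = character(0), pocket = character(0),
                      position = integer(0))
  class(out) <- c("contact_record", "data.frame")
  out
}

#' Union per-pocket contact positions over many complexes
#'
#' @param records One or more `contact_record` data.frames (rbind-compatible),
#'   typically one per complex structure.
#' @return A [pocket_table()] whose pocket `p` holds the sorted union of `p`'s
#'   contact positions over all records.  Every pocket must be hit by at
#'   least one complex.
#' @export
union_positions <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records) == 0L) stop("no contact records supplied")
  all <- do.call(rbind, lapply(records, as.data.frame))
  if (nrow(all) == 0L) stop("no contact records supplied")
  entries <- lapply(POCKET_IDS, function(p)
    sort(unique(all$position[all$pocket == p])))
  names(entries) <- POCKET_IDS
  empty <- POCKET_IDS[lengths(entries) == 0L]
  if (length(empty))
    stop("no contacts observed for pocket(s): ", paste(empty, collapse = ", "))
  pocket_table(entries)
}

#' Write contact records as TSV
#'
#' One row per complex with nine pocket columns (comma-separated positions),
#' plus a final `union` row.
#'
#' @param records List of `contact_record` data.frames.
#' @param path Output path.
#' @export
write_contact_records <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  all <- do.call(rbind, lapply(records, as.data.frame))
  fmt <- function(df) vapply(POCKET_IDS, function(p)
    paste(sort(unique(df$position[df$pocket == p])), collapse = ","),
    character(1L))
  lines <- paste(c("pdb_id", POCKET_IDS), collapse = "\t")
  for (id in unique(all$pdb_id))
    lines <- c(lines, paste(c(id, fmt(all[all$pdb_id == id, ])), collapse = "\t"))
  lines <- c(lines, paste(c("union", fmt(all)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
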