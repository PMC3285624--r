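# Synthetic fixtures: a stated world of alleles, matrices and peptides that
# lets the whole extrapolation pipeline be exercised without the external
# matrix library, IMGT/HLA sequences or binding databases.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Residue-effect model shared by library generation: each (pocket, position,
# residue) triple maps to a fixed 20-vector of effects drawn once from the
# seed, so an allele's pocket vector is a deterministic function of its
# pseudosequence — similar pseudosequences yield similar matrices.
pocket_effects <- function(table, seed, scale = 2) {
  with_seed(seed, {
    lapply(stats::setNames(POCKET_IDS, POCKET_IDS), function(p) {
      n <- length(table[[p]])
      lapply(seq_len(n), function(i) {
        e <- matrix(stats::rnorm(400, sd = scale / sqrt(n)), 20L, 20L,
                    dimnames = list(AA_ALPHABET, AA_ALPHABET))
        e
      })
    })
  })
}

vector_from_pseq <- function(pseq, effects_p) {
  res <- strsplit(pseq, "", fixed = TRUE)[[1L]]
  v <- numeric(20L)
  for (i in seq_along(res)) v <- v + effects_p[[i]][res[[i]], ]
  v
}

#' Generate a synthetic matrix library with controllable allele similarity
#'
#' Emulates the real setting: a handful of "characterized" alleles, each with
#' an aligned beta1-domain sequence and a 20 x 9 specificity matrix.  All
#' alleles derive from one base sequence; at every pocket contact position a
#' residue is resampled uniformly with probability `1 - similarity_level`, so
#' `similarity_level = 1` gives identical pseudosequences and `0` gives
#' independent ones.  Each allele's pocket vector is a deterministic function
#' of its pseudosequence (a sum of per-position residue effects), so matrix
#' similarity tracks pseudosequence similarity and identical pseudosequences
#' imply identical matrices.
#'
#' @param n_alleles Number of library alleles (>= 1).
#' @param similarity_level Inter-allele pseudosequence similarity in \[0, 1\].
#' @param seed Integer seed; the fixture is deterministic given it.
#' @param table Pocket table (default [default_pocket_table()]).
#' @param mask Unused-pocket mask (default `{P5, P8}`).
#' @param scale Typical magnitude of matrix entries.
#' @return List with `library` (a [matrix_library()]), `sequences` (named
#'   character vector of aligned allele sequences), `pseudosequences` (named
#'   list), `table`, and `effects` (the residue-effect model, reusable to
#'   build ground-truth matrices for new pseudosequences).
#' @export
generate_fixture_library <- function(n_alleles, similarity_level = 0.7,
                                     seed = 1L,
                                     table = default_pocket_table(),
                                     mask = DEFAULT_UNUSED_POCKETS,
                                     scale = 2) {
  stopifnot(n_alleles >= 1L,
            similarity_level >= 0, similarity_level <= 1)
  effects <- pocket_effects(table, seed = seed + 1L, scale = scale)
  maxpos <- max(unlist(table))
  pocket_pos <- sort(unique(unlist(table)))
  with_seed(seed, {
    base <- sample(AA_ALPHABET, maxpos, replace = TRUE)
    alleles <- sprintf("DRB1*9%d:%02d", seq_len(n_alleles) %/% 100L,
                       seq_len(n_alleles) %% 100L)
    sequences <- vapply(seq_len(n_alleles), function(i) {
      s <- base
      flip <- pocket_pos[stats::runif(length(pocket_pos)) > similarity_level]
      s[flip] <- sample(AA_ALPHABET, length(flip), replace = TRUE)
      paste(s, collapse = "")
    }, character(1L))
    names(sequences) <- alleles
  })
  pseqs <- lapply(sequences, extract_pseudosequences, table = table)
  pssms <- lapply(alleles_of(pseqs), function(a) {
    m <- vapply(POCKET_IDS, function(p)
      vector_from_pseq(pseqs[[a]][[p]], effects[[p]]), numeric(20L))
    rownames(m) <- AA_ALPHABET
    m
  })
  names(pssms) <- names(pseqs)
  list(library = matrix_library(pssms, mask = mask),
       sequences = sequences,
       pseudosequences = pseqs,
       table = table,
       effects = effects)
}

alleles_of <- function(pseqs) stats::setNames(names(pseqs), names(pseqs))

#' Ground-truth PSSM for an arbitrary pseudosequence under a fixture's model
#'
#' Applies the fixture's residue-effect model to any pseudosequence set,
#' giving the matrix an allele "truly" has in the synthetic world — useful as
#' the generating matrix of benchmarks for query alleles outside the library.
#'
#' @param pseqs Named character vector of 9 pseudosequences.
#' @param fixture Result of [generate_fixture_library()].
#' @param allele Name recorded on the PSSM.
#' @return A [pssm()].
#' @export
fixture_true_pssm <- function(pseqs, fixture, allele = "<query>") {
  m <- vapply(POCKET_IDS, function(p)
    vector_from_pseq(pseqs[[p]], fixture$effects[[p]]), numeric(20L))
  rownames(m) <- AA_ALPHABET
  pssm(m, allele = allele, mask = fixture$library$mask)
}

# Sample one 9-mer core per row proportional to exp(beta) per pocket.
sample_cores <- function(pssm, n, noise = 0) {
  vals <- unclass(pssm)
  cores <- matrix("", n, 9L)
  for (p in 1:9) {
    pr <- exp(vals[, p]); pr <- pr / sum(pr)
    cores[, p] <- sample(AA_ALPHABET, n, replace = TRUE, prob = pr)
  }
  if (noise > 0) {
    flip <- matrix(stats::runif(n * 9L) < noise, n, 9L)
    cores[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
  }
  apply(cores, 1L, paste, collapse = "")
}

#' Generate a synthetic benchmark from a generating PSSM
#'
#' Binder 9-mers are sampled per pocket with probability proportional to
#' `exp(beta_p)`, so the generating matrix truly ranks them above the
#' uniformly random decoys; `noise` resamples each binder residue uniformly
#' with the given probability.
#'
#' @param pssm Generating [pssm()].
#' @param n_binders,n_decoys Counts (each >= 1).
#' @param noise Per-residue corruption probability in \[0, 1\] (default 0).
#' @param seed Integer seed.
#' @param allele Allele name stamped on the records (defaults to the PSSM's).
#' @return data.frame with columns `allele`, `peptide`, `label`.
#' @export
generate_fixture_benchmark <- function(pssm, n_binders, n_decoys, noise = 0,
                                       seed = 1L,
                                       allele = attr(pssm, "allele")) {
  stopifnot(n_binders >= 1L, n_decoys >= 1L, noise >= 0, noise <= 1)
  with_seed(seed, {
    binders <- sample_cores(pssm, n_binders, noise = noise)
    decoys <- apply(matrix(sample(AA_ALPHABET, n_decoys * 9L, replace = TRUE),
                           n_decoys), 1L, paste, collapse = "")
    data.frame(allele = allele,
               peptide = c(binders, decoys),
               label = rep(c(TRUE, FALSE), c(n_binders, n_decoys)))
  })
}

#' Generate peptides with planted binding cores
#'
#' Each peptide is a high-scoring core (sampled as in
#' [generate_fixture_benchmark()]) embedded between uniformly random flanks
#' of random length, with the true offset recorded — the desk-scale stand-in
#' for crystallographically determined binding cores.
#'
#' @param pssm Generating [pssm()].
#' @param n Number of peptides.
#' @param flank_min,flank_max Flank length range (each side, inclusive).
#' @param seed Integer seed.
#' @return data.frame with columns `peptide`, `core`, `core_start` (0-based).
#' @export
generate_planted_cores <- function(pssm, n, flank_min = 2L, flank_max = 6L,
                                   seed = 1L) {
  stopifnot(n >= 1L, flank_min >= 0L, flank_max >= flank_min)
  with_seed(seed, {
    cores <- sample_cores(pssm, n)
    left <- sample(flank_min:flank_max, n, replace = TRUE)
    right <- sample(flank_min:flank_max, n, replace = TRUE)
    rnd <- function(k) paste(sample(AA_ALPHABET, k, replace = TRUE),
                             collapse = "")
    peptide <- vapply(seq_len(n), function(i)
      paste0(rnd(left[[i]]), cores[[i]], rnd(right[[i]])), character(1L))
    data.frame(peptide = peptide, core = cores, core_start = left)
  })
}

#' Write aligned allele sequences as FASTA
#'
#' @param sequences Named character vector (names = allele names).
#' @param path Output path.
#' @export
write_allele_fasta <- function(sequences, path) {
  writeLines(as.vector(rbind(paste0(">", names(sequences)), sequences)), path)
  invisible(path)
}
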