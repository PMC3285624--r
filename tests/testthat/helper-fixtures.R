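# Shared helpers: tiny deterministic objects built in code.

# An aligned DRB sequence consisting of one repeated residue.
const_seq <- function(res = "A", len = 90L) paste(rep(res, len), collapse = "")

# Pseudosequences of a constant-residue allele.
const_pseqs <- function(res = "A") extract_pseudosequences(const_seq(res))

# A PSSM with a single non-zero entry.
unit_pssm <- function(aa, pocket, value = 1, mask = character(0)) {
  m <- matrix(0, 20L, 9L, dimnames = list(AA_ALPHABET, POCKET_IDS))
  m[aa, pocket] <- value
  pssm(m, allele = "DRB1*99:99", mask = mask)
}

# Deterministic dense PSSM (entries depend on seed), no mask.
random_pssm <- function(seed, scale = 1, mask = character(0)) {
  set.seed(seed)
  m <- matrix(stats::rnorm(180, sd = scale), 20L, 9L,
              dimnames = list(AA_ALPHABET, POCKET_IDS))
  pssm(m, allele = "DRB1*98:01", mask = mask)
}

# Worst-case partner: for each query residue pick the amino acid minimizing
# the BLOSUM62 score (independent construction used by the endpoint tests).
worst_partner <- function(pseq, b62 = read_substitution_matrix()) {
  res <- strsplit(pseq, "", fixed = TRUE)[[1L]]
  paste(vapply(res, function(a) AA_ALPHABET[which.min(b62[a, ])],
               character(1L)), collapse = "")
}

# Bare numeric values of a PSSM, stripped of allele/mask/profile attributes.
pssm_values <- function(p) {
  v <- unclass(p)
  attributes(v) <- attributes(v)[c("dim", "dimnames")]
  v
}

# Brute-force pair-counting oracle for the AUC (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Minimal PDB writer for synthetic coordinate fixtures.
# atoms: data.frame(atom, resname, chain, resseq, x, y, z, element)
write_synthetic_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    with(atoms[i, ], sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, atom, resname, chain, resseq, x, y, z, 1.0, 0.0, element))
  }, character(1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
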