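---
title: "Pocket-based PSSM extrapolation for HLA-DR: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket-based PSSM extrapolation for HLA-DR: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpan)
```

## The model

HLA-DR binding specificity is, to a useful approximation, *pocket-additive*:
a 9-mer core residue interacts with one of nine pockets, each pocket
contributes independently to the binding score, and a pocket's preference is
determined by the handful of polymorphic MHC residues lining it. `drpan`
operationalizes this in three steps.

**1. Pockets as pseudosequences.** Each pocket is defined by the β1-domain
positions whose residues contact the corresponding core residue (within 4 Å
in crystal structures of HLA–peptide complexes); `default_pocket_table()`
holds the union over 32 complexes. An allele's pocket pseudosequence is its
amino acids at those positions, extracted from a pre-aligned β1-domain
sequence. Pre-alignment is a deliberate contract: leader-peptide offsets and
alignment algorithms vary between sequence sources, so the package requires
`character k = mature position k` rather than guessing, and the
`contact_derivation` functions let a user regenerate the pocket table (with a
per-structure numbering `offset`) when their structures use other numbering.

**2. Pocket similarity and weights.** Raw similarity is the BLOSUM62 sum
over pseudosequence positions. The normalization to $[0,1]$ is stated in the
source literature only through its endpoints (1 for identical, 0 for totally
distinctive pseudosequences); we use the per-position min–max form
$$S_p(q,l) = \frac{1}{|p|}\sum_i \frac{B(q_i,l_i) - m_i}{M_i - m_i},
\qquad M_i = B(q_i,q_i),\; m_i = \min_b B(q_i,b),$$
which provably attains both endpoints for *every* query (the BLOSUM62
diagonal dominates its row, a fact asserted in the test suite) and is
monotone in the raw score at each position. It is asymmetric — the first
argument is always the query — which is documented rather than hidden,
because symmetrizing would break the exact self-similarity endpoint. Weights
are the sharpened convex coefficients $w \propto S^\alpha$: the only form
that is scale-free in $S$, satisfies the positive-$\alpha$ constraint, and
converges to the 1-KNN rule as $\alpha \to \infty$ (available directly via
`alpha = Inf`, with ties averaged). Numeric parity with the original
authors' server for *non-identical* pseudosequences is not guaranteed, since
their exact algebra is not recoverable from the published text; every stated
property of it is satisfied and tested.

**3. Weighted averaging per pocket.** The query's pocket vector is the
weighted average of library vectors *of that pocket* — weights are pocket
specific, not one global allele weight, so a query can resemble one allele at
P1 and another at P9. Pockets P5 and P8 carry no information in the
classical library and stay zero; the mask is configurable because public
redistributions of the classical matrices disagree about which non-anchor
columns are zero.

## Tunable parameters

* **`alpha` (default 9, dimensionless).** Controls how sharply similar
  library alleles dominate. The default follows the published selection on
  an external benchmark (best average AUC at α = 9–10, kept at 9
  throughout). `alpha_sweep()` reproduces the selection protocol on any
  benchmark; the acceptance suite checks only the qualitative shape
  (moderate α ≥ α = 1 and ≥ 1-KNN) on synthetic data.
* **`cutoff` (4.0 Å, inclusive).** Contact distance for pocket derivation.
  Heavy atoms only by default (`heavy_only = TRUE`); whether the original
  derivation included hydrogens is unstated, so it is a flag, not a guess
  fixed in code.
* **`threshold_nM` (100 or 1000 nM).** Affinity-to-label cutoff, boundary
  inclusive (≤). Per-allele thresholds are supported because published
  benchmarks mix 100 nM (for a few well-characterized alleles) and 1000 nM.
* **Unused-pocket `mask` (`{P5, P8}`).** See above.
* **Motif sampling** (`n_peptides = 100000`, `top_fraction = 0.01`,
  `length = 9`): mirrors the published logo protocol — generate a random
  pool, keep the top 1% by score, tally per-pocket frequencies. The
  background is uniform by default with injectable empirical frequencies
  (the original sampled a proteome database, which is not bundled); whether
  the original realigned longer peptides on predicted cores is unstated, so
  both are supported and the default peptide length of 9 makes the question
  moot.

## Numerical and convention choices

* Window-score ties break to the *leftmost* offset — deterministic and
  conventional for PSSM scanners; the literature is silent.
* Unknown residues (`X`, common in crystallographic peptides) contribute 0
  to their pocket during scanning, so such peptides scan verbatim; in an
  *allele* sequence at a pocket position, `X` is an error, because no
  pseudosequence exists.
* A query pocket with zero similarity to every library allele raises an
  error rather than dividing by zero.
* The contact test uses squared distances with a `1e-12` slack on the
  squared cutoff so that an exactly-4.0 Å pair is inclusive under floating
  point.
* Weights sum to 1 within `1e-12` per pocket (asserted in tests); matrices
  are written with 15 significant digits so the library TSV round-trips to
  `1e-12`.

## The synthetic world

The fixture generator emulates the real setting's *structure*, not its
biology: alleles descend from one base sequence with pocket residues
resampled at rate `1 - similarity_level`; each allele's pocket vector is a
deterministic sum of per-position residue effects, so matrix similarity
tracks pseudosequence similarity — the core assumption of the method, made
true by construction. Benchmarks sample binder cores per pocket with
probability ∝ exp(β) and uniform decoys; planted-core peptides embed such
cores in random flanks.

A green test therefore establishes that the machinery is correct *given the
pocket-additive assumption*: weights, averaging, scanning and the statistics
do what the model says. It does **not** establish real-world predictive
accuracy — real pocket specificities are not a linear function of contact
residues, real binders have flanking-residue effects, and real affinity data
are noisy and biased. The published external-benchmark AUCs (≈ 0.7–0.76
averages) depend on datasets that are deliberately not bundled; the harness
accepts them as TSV (`read_benchmark()`) when a user has them. Defaults in
the generator were chosen once as a realistic moderate regime (similarity
0.5–0.7, benchmarks of tens to hundreds of peptides, per-residue noise 0.3
for the α-sweep world) and are documented in the tests that use them.

## Limitations

* DRB loci only; DP/DQ and non-human MHC-II are out of scope (the pocket
  table and nomenclature handling are DR-specific).
* The real experimentally derived 11-allele matrix library is not
  redistributed; it drops in as a library TSV (`read_matrix_library()`),
  after which `count_unique_vectors()` should report the known sharing
  structure (35 distinct non-masked vectors).
* Extrapolation quality degrades for queries dissimilar to the whole
  library — the published evaluations show exactly this on novel-allele
  subsets — and nothing in the method flags low-confidence queries beyond
  the similarity profile attached to every synthesized PSSM; inspect it.
* No peptide-flanking effects, no quantitative affinity regression: scores
  rank peptides within an allele and locate cores, they are not calibrated
  nM predictions.
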