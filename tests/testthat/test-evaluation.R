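test_that("auc reproduces hand-computed and degenerate cases", {
  expect_identical(auc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1)
  expect_identical(auc(c(1, 2, 9, 10), c(1, 1, 0, 0)), 0)
  expect_equal(auc(c(3, 1, 2), c(1, 0, 1)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 0, 1)), 0.5)
  expect_equal(auc(c(5, 5), c(1, 0)), 0.5)     # tie counts one half
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auc equals the pair-counting oracle on random instances", {
  set.seed(97)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    scores <- sample(1:8, n, replace = TRUE)  # coarse scores force ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("affinity thresholding is boundary-inclusive and per-allele", {
  rec <- data.frame(allele = c("DRB1*01:01", "DRB1*01:01", "DRB1*03:01"),
                    peptide = c("A", "B", "C"),
                    affinity_nM = c(50, 100, 500))
  lab <- threshold_labels(rec, 100)
  expect_identical(lab$label, c(TRUE, TRUE, FALSE))

  thr <- c("DRB1*01:01" = 100, default = 1000)
  lab2 <- threshold_labels(rec, thr)
  expect_identical(lab2$label, c(TRUE, TRUE, TRUE))

  expect_error(threshold_labels(rec, c("DRB1*01:01" = 100)), "no threshold")
  rec$affinity_nM[1] <- NA
  expect_error(threshold_labels(rec, 100), "affinity")
})

test_that("the one-tailed binomial test matches exact tail sums", {
  expect_equal(per_allele_binomial(9, 1), 11 / 1024)
  for (n in 1:12) expect_equal(per_allele_binomial(n, 0), 2^-n)
  expect_gt(per_allele_binomial(5, 5), 0.5)
  expect_error(per_allele_binomial(0, 0), "ties")

  # exact tail summation oracle for all n <= 30
  for (n in 1:30) {
    wins <- sample(0:n, 1)
    tail <- sum(choose(n, wins:n)) / 2^n
    expect_equal(per_allele_binomial(wins, n - wins), tail)
  }
  # cross-check against stats::binom.test on a few cases
  for (w in c(3, 7, 12)) {
    expect_equal(per_allele_binomial(w, 15 - w),
                 stats::binom.test(w, 15, alternative = "greater")$p.value)
  }
})

test_that("core errors require exact offsets", {
  truth <- data.frame(id = c("s1", "s2", "s3"),
                      peptide = c("AAAWNDFYKLMAA", "CCWNDFYKLMC",
                                  "ENPVVHFFKNIVTPR"),
                      core_start = c(3L, 2L, 4L))
  good <- data.frame(peptide = truth$peptide, core_start = c(3L, 2L, 4L))
  expect_identical(core_error_count(good, truth)$n_errors, 0L)

  shifted <- data.frame(peptide = truth$peptide, core_start = c(3L, 3L, 4L))
  res <- core_error_count(shifted, truth)
  expect_identical(res$n_errors, 1L)
  expect_identical(res$report$id[res$report$error], "s2")

  expect_error(core_error_count(good[1:2, ], truth), "length")
  bad <- good; bad$peptide[1] <- "XXXXXXXXX"
  expect_error(core_error_count(bad, truth), "mismatch.*row 1")
})

test_that("a known crystallographic core is recovered from its peptide", {
  # myelin basic protein peptide bound to DRB1*15:01 (structure 1BX2):
  # core VHFFKNIVT at 0-based offset 4 within ENPVVHFFKNIVTPR
  pep <- "ENPVVHFFKNIVTPR"
  core <- "VHFFKNIVT"
  expect_identical(substr(pep, 5, 13), core)
  m <- matrix(0, 20, 9, dimnames = list(AA_ALPHABET, POCKET_IDS))
  for (p in 1:9) m[substr(core, p, p), p] <- 2   # PSSM rewarding that core
  res <- scan_peptide(pssm(m, mask = character(0)), pep)
  expect_identical(res$core_start, 4L)
  expect_identical(res$core, core)
})

test_that("fixture libraries are deterministic and respect similarity_level", {
  a <- generate_fixture_library(4, 0.5, seed = 101)
  b <- generate_fixture_library(4, 0.5, seed = 101)
  expect_identical(a$sequences, b$sequences)
  expect_equal(lapply(a$library$pssms, pssm_values),
               lapply(b$library$pssms, pssm_values))

  same <- generate_fixture_library(4, 1, seed = 103)
  expect_identical(length(unique(same$pseudosequences)), 1L)
  # identical pseudosequences imply identical matrices
  expect_equal(pssm_values(same$library$pssms[[1]]),
               pssm_values(same$library$pssms[[4]]))

  # similarity 0 draws pocket residues independently: pseudosequences differ
  free <- generate_fixture_library(6, 0, seed = 105)
  expect_gt(length(unique(free$pseudosequences)), 1L)

  expect_error(generate_fixture_library(0, 0.5), "n_alleles")
})

test_that("fixture benchmarks separate binders from decoys", {
  fx <- generate_fixture_library(3, 0.6, seed = 107)
  gen <- fx$library$pssms[[1]]
  bench <- generate_fixture_benchmark(gen, 40, 40, seed = 109)
  sc <- scan_peptides(gen, bench$peptide)$score
  expect_gt(mean(sc[bench$label]), mean(sc[!bench$label]))

  # the generating PSSM outranks an unrelated random PSSM on its own fixture
  other <- random_pssm(991)
  sc2 <- scan_peptides(other, bench$peptide)$score
  expect_gt(auc(sc, bench$label), auc(sc2, bench$label))

  # determinism and validation
  again <- generate_fixture_benchmark(gen, 40, 40, seed = 109)
  expect_identical(bench, again)
  expect_error(generate_fixture_benchmark(gen, 0, 10), "n_binders")
})

test_that("synthesized PSSMs recover planted binders end to end", {
  # query copies a library allele whose matrix generated the binders
  fx <- generate_fixture_library(5, 0.5, seed = 111)
  star <- names(fx$library$pssms)[2]
  bench <- generate_fixture_benchmark(fx$library$pssms[[star]], 60, 60,
                                      seed = 113)
  syn <- synthesize_pssm(fx$pseudosequences[[star]], fx$library,
                         fx$pseudosequences, alpha = 9)
  sc <- scan_peptides(syn, bench$peptide)$score
  expect_gt(auc(sc, bench$label), 0.9)
})

test_that("per-allele evaluation reports count, binder and AUC", {
  fx <- generate_fixture_library(2, 0.6, seed = 115)
  b1 <- generate_fixture_benchmark(fx$library$pssms[[1]], 20, 20, seed = 117)
  b2 <- generate_fixture_benchmark(fx$library$pssms[[2]], 15, 25, seed = 119)
  rec <- rbind(b1, b2)
  rep <- evaluate_benchmark(rec, fx$library$pssms)
  expect_identical(names(rep), c("allele", "count", "binder", "auc"))
  expect_identical(rep$count, c(40L, 40L))
  expect_identical(rep$binder, c(20L, 15L))
  expect_true(all(rep$auc > 0.5))

  # single-class allele reports NA instead of crashing
  rec1 <- b1[b1$label, ]
  rep1 <- evaluate_benchmark(rec1, fx$library$pssms)
  expect_true(is.na(rep1$auc))
  expect_error(evaluate_benchmark(data.frame(allele = "DRB1*55:55",
                                             peptide = "ACDEFGHIK",
                                             label = TRUE),
                                  fx$library$pssms), "no PSSM")
})

test_that("benchmark TSV round trips and validates its schema", {
  rec <- data.frame(allele = "DRB1*01:01",
                    peptide = c("ACDEFGHIK", "WNDFYKLMH"),
                    affinity_nM = c(50, 5000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(rec, path)
  back <- read_benchmark(path)
  expect_equal(back, rec)
  writeLines("allele\tpeptide\nDRB1*01:01\tACDEFGHIK", path)
  expect_error(read_benchmark(path), "affinity_nM or label")
})
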