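test_that("pssm constructor enforces shape, order and the unused mask", {
  m <- matrix(seq_len(180) / 10, 20L, 9L,
              dimnames = list(AA_ALPHABET, POCKET_IDS))
  p <- pssm(m, allele = "DRB1*01:01")
  expect_true(all(unclass(p)[, c("P5", "P8")] == 0))
  expect_identical(rownames(p), AA_ALPHABET)

  # shuffled dimnames are reordered, not misassigned
  shuffled <- m[rev(AA_ALPHABET), rev(POCKET_IDS)]
  expect_equal(pssm_values(pssm(shuffled, mask = character(0))), m)

  expect_error(pssm(m[1:19, ]), "20 x 9")
  m2 <- m; m2[1, 1] <- NA
  expect_error(pssm(m2), "finite")
})

test_that("matrix library round trips through the TSV format", {
  fx <- generate_fixture_library(3, 0.6, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_library(fx$library, path)
  back <- read_matrix_library(path)
  expect_identical(names(back$pssms), names(fx$library$pssms))
  for (a in names(back$pssms))
    expect_equal(pssm_values(back$pssms[[a]]), pssm_values(fx$library$pssms[[a]]),
                 tolerance = 1e-12)
  expect_identical(back$mask, fx$library$mask)

  # single all-zero allele loads as an all-zero PSSM
  lines <- c(paste(c("allele", "pocket", AA_ALPHABET), collapse = "\t"),
             vapply(setdiff(POCKET_IDS, DEFAULT_UNUSED_POCKETS), function(p)
               paste(c("DRB1*01:01", p, rep("0", 20)), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  zl <- read_matrix_library(path)
  expect_identical(length(zl$pssms), 1L)
  expect_true(all(unclass(zl$pssms[[1]]) == 0))
})

test_that("library loader reports malformed files with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  head <- paste(c("allele", "pocket", AA_ALPHABET), collapse = "\t")
  row <- function(a, p, v = rep("0", 20)) paste(c(a, p, v), collapse = "\t")

  writeLines(c(head, row("DRB1*01:01", "P1", rep("x", 20))), path)
  expect_error(read_matrix_library(path), "line 2.*malformed")

  writeLines(c(head, paste(c("DRB1*01:01", "P1", rep("0", 19)),
                           collapse = "\t")), path)
  expect_error(read_matrix_library(path), "line 2.*22 fields")

  writeLines(c(head, row("DRB1*01:01", "P1"), row("DRB1*01:01", "P1")), path)
  expect_error(read_matrix_library(path), "line 3.*duplicate pocket")

  # a pocket outside the mask may not be omitted
  writeLines(c(head, row("DRB1*01:01", "P1")), path)
  expect_error(read_matrix_library(path), "missing pocket")

  expect_error(matrix_library(list(`DRB1*01:01` = matrix(0, 20, 9),
                                   `DRB1*0101` = matrix(0, 20, 9))),
               "duplicate allele")
})

test_that("synthesis reduces to identity for a single-allele library", {
  fx <- generate_fixture_library(1, 1, seed = 3)
  qp <- const_pseqs("C")
  for (a in c(1, 9, 50)) {
    syn <- synthesize_pssm(qp, fx$library, fx$pseudosequences, alpha = a)
    expect_equal(pssm_values(syn), pssm_values(fx$library$pssms[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("equal weights average the library vectors arithmetically", {
  m1 <- matrix(1, 20, 9); m2 <- matrix(3, 20, 9)
  lib <- matrix_library(list(`DRB1*95:01` = m1, `DRB1*95:02` = m2),
                        mask = character(0))
  ps <- const_pseqs("A")
  twin_pseqs <- list(`DRB1*95:01` = const_pseqs("S"),
                     `DRB1*95:02` = const_pseqs("S"))
  syn <- synthesize_pssm(const_pseqs("A"), lib, twin_pseqs, alpha = 9)
  expect_true(all(abs(unclass(syn) - 2) < 1e-12))
})

test_that("alpha = 1000 copies the most similar allele's matrix (1-KNN limit)", {
  fx <- generate_fixture_library(6, 0.5, seed = 17)
  star <- names(fx$library$pssms)[4]
  syn <- synthesize_pssm(fx$pseudosequences[[star]], fx$library,
                         fx$pseudosequences, alpha = 1000)
  expect_lt(max(abs(unclass(syn) - unclass(fx$library$pssms[[star]]))), 1e-6)
})

test_that("synthesized vectors are convex combinations and scale linearly", {
  fx <- generate_fixture_library(5, 0.5, seed = 23)
  qp <- const_pseqs("L")
  syn <- synthesize_pssm(qp, fx$library, fx$pseudosequences, alpha = 9)
  stack <- sapply(fx$library$pssms, unclass, simplify = "array")
  lo <- apply(stack, c(1, 2), min); hi <- apply(stack, c(1, 2), max)
  expect_true(all(unclass(syn) >= lo - 1e-12))
  expect_true(all(unclass(syn) <= hi + 1e-12))

  scaled <- matrix_library(lapply(fx$library$pssms, function(m)
    unclass(m) * 2.5), mask = fx$library$mask)
  syn2 <- synthesize_pssm(qp, scaled, fx$pseudosequences, alpha = 9)
  expect_equal(pssm_values(syn2), pssm_values(syn) * 2.5, tolerance = 1e-12)
})

test_that("synthesis varies continuously over an alpha grid", {
  fx <- generate_fixture_library(5, 0.5, seed = 29)
  qp <- const_pseqs("V")
  grid <- seq(4, 6, by = 0.5)
  mats <- lapply(grid, function(a)
    unclass(synthesize_pssm(qp, fx$library, fx$pseudosequences, alpha = a)))
  steps <- vapply(seq_along(grid)[-1], function(i)
    max(abs(mats[[i]] - mats[[i - 1]])), numeric(1))
  # small alpha steps produce small matrix steps
  expect_true(all(steps < 0.2))
})

test_that("unique-vector counting reports sharing structure", {
  fx <- generate_fixture_library(1, 1, seed = 31, mask = character(0))
  lib1 <- fx$library
  expect_identical(count_unique_vectors(lib1)$n_unique, 9L)

  # two alleles with identical matrices share all vectors
  twin <- matrix_library(list(`DRB1*94:01` = unclass(lib1$pssms[[1]]),
                              `DRB1*94:02` = unclass(lib1$pssms[[1]])),
                         mask = character(0))
  cu <- count_unique_vectors(twin)
  expect_identical(cu$n_unique, 9L)
  expect_true(all(lengths(cu$groups) == 2L))

  # masking P5/P8 removes the shared zero columns from the count
  masked <- matrix_library(list(`DRB1*94:01` = unclass(lib1$pssms[[1]])))
  expect_identical(count_unique_vectors(masked)$n_unique, 7L)
})
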