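dna <- function(...) Biostrings::DNAStringSet(c(...))

test_that("codon counting walks in-frame triplets with the length filter", {
  ct <- countCodons(dna(a = "ATGAAAAAATGA"), minLen = 0)
  expect_equal(unname(codonCounts(ct)[c("ATG", "AAA", "TGA")]),
               c(1L, 2L, 1L))
  expect_equal(sum(codonCounts(ct)), 4L)

  # middle triplet contains N: skipped, not fatal
  ct2 <- countCodons(dna(a = "ATGAANAAA"), minLen = 0)
  expect_equal(unname(codonCounts(ct2)[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(codonCounts(ct2)), 2L)
  expect_equal(ct2@nTripletsSkipped, 1L)

  # trailing 1-2 nt dropped
  ct3 <- countCodons(dna(a = "ATGAA"), minLen = 0)
  expect_equal(sum(codonCounts(ct3)), 1L)

  # 299 bp sequence falls to the default 300 nt filter
  short <- paste(rep("ATG", 100), collapse = "")
  short <- substr(short, 1, 299)
  ct4 <- countCodons(dna(a = short, b = paste(rep("AAA", 100),
                                              collapse = "")))
  expect_equal(nSequencesFiltered(ct4), 1L)
  expect_equal(nSequencesUsed(ct4), 1L)
  expect_equal(unname(codonCounts(ct4)[["ATG"]]), 0L)
  expect_error(countCodons(dna(a = "ATG"), minLen = 300),
               "lower minLen", class = "txpValidationError")
})

test_that("codon counting is additive over disjoint sequence sets", {
  set.seed(21)
  mk <- function(n) {
    s <- vapply(seq_len(n), function(i)
      paste0(sample(c("A", "C", "G", "T"), 3 * sample(5:50, 1), TRUE),
             collapse = ""), character(1))
    Biostrings::DNAStringSet(setNames(s, sprintf("s%d", seq_len(n))))
  }
  a <- mk(10); b <- mk(7)
  ca <- codonCounts(countCodons(a, minLen = 0))
  cb <- codonCounts(countCodons(b, minLen = 0))
  cab <- codonCounts(countCodons(c(a, b), minLen = 0))
  expect_equal(cab, ca + cb)
})

test_that("RSCU matches the formula on worked examples", {
  # Lys counts AAA=3, AAG=1: mean 2 -> RSCU 1.5 / 0.5
  counts <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  counts[c("AAA", "AAG")] <- c(3L, 1L)
  counts["ATG"] <- 5L
  r <- rscuValues(rscu(makeCountTable(counts)))
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))
  expect_equal(unname(r[["ATG"]]), 1.0)  # single-codon amino acid
  # unobserved families are NA, not 0 or 1
  expect_true(is.na(r[["TGG"]]))
  # equal synonymous counts mean no bias
  eq <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  eq[c("GGA", "GGC", "GGG", "GGT")] <- 7L
  expect_equal(unname(rscuValues(rscu(makeCountTable(eq)))[
    c("GGA", "GGC", "GGG", "GGT")]), rep(1, 4))
})

test_that("family RSCU values sum to the family size (1,000 tables)", {
  gc <- Biostrings::GENETIC_CODE
  set.seed(42)
  for (i in 1:1000) {
    r <- rscuValues(rscu(makeCountTable(randomCounts())))
    for (aa in setdiff(unique(gc), "*")) {
      fam <- names(gc)[gc == aa]
      vals <- r[fam]
      if (all(is.na(vals))) next
      expect_lt(abs(sum(vals) - length(fam)), 1e-9)
    }
  }
})

test_that("rscu agrees with an independent brute-force oracle", {
  set.seed(7)
  for (i in 1:1000) {
    counts <- randomCounts()
    expect_equal(rscuValues(rscu(makeCountTable(counts))),
                 bruteRscu(counts))
  }
})

test_that("rscu agrees with seqinr's implementation on a random CDS", {
  skip_if_not_installed("seqinr")
  set.seed(3)
  s <- paste0(sample(names(Biostrings::GENETIC_CODE), 500, TRUE),
              collapse = "")
  mine <- rscuValues(rscu(countCodons(dna(a = s), minLen = 0)))
  ref <- seqinr::uco(seqinr::s2c(s), index = "rscu")
  ref <- ref[tolower(names(mine))]
  keep <- !is.na(mine)
  expect_equal(unname(mine[keep]), unname(ref[keep]), tolerance = 1e-12)
})

test_that("stop codons form a family only on request", {
  counts <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  counts[c("TAA", "TAG", "TGA")] <- c(2L, 1L, 1L)
  counts["ATG"] <- 1L
  noStop <- rscuValues(rscu(makeCountTable(counts)))
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(noStop)))
  withStop <- rscuValues(rscu(makeCountTable(counts), includeStop = TRUE))
  expect_equal(unname(withStop[c("TAA", "TAG", "TGA")]), c(1.5, 0.75, 0.75))
})

test_that("bias statistics report range, extremes and population SD", {
  counts <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  counts[c("AAA", "AAG")] <- c(3L, 1L)   # RSCU 1.5 / 0.5
  counts["ATG"] <- 2L
  st <- biasStats(rscu(makeCountTable(counts)))
  k <- st[st$amino_acid == "K", ]
  expect_equal(k$rscu_range, 1.0)
  expect_equal(k$rscu_min, 0.5)
  expect_equal(k$rscu_sd, 0.5)           # population SD of {1.5, 0.5}
  expect_equal(k$min_codon, "AAG")
  expect_equal(k$max_codon, "AAA")
  m <- st[st$amino_acid == "M", ]
  expect_equal(m$rscu_range, 0)
  expect_equal(m$rscu_sd, 0)
  expect_false("W" %in% st$amino_acid)   # unobserved -> omitted
})

test_that("cross-sample comparison aligns codons and checks sample ids", {
  counts <- randomCounts()
  t1 <- rscu(makeCountTable(counts, "a"))
  t2 <- rscu(makeCountTable(counts, "b"))
  cmp <- compareSamples(list(t1, t2))
  expect_equal(dim(cmp$rscu), c(61L, 2L))
  expect_equal(cmp$rscu[, "a"], cmp$rscu[, "b"])
  expect_true(all(cmp$range[, "a"] == cmp$range[, "b"], na.rm = TRUE))
  one <- compareSamples(list(t1))
  expect_equal(unname(one$rscu[, 1]), unname(rscuValues(t1)[
    rownames(one$rscu)]))
  expect_error(compareSamples(list(t1, t1)),
               class = "txpValidationError")
  # per-amino-acid row sums of the export equal the family size
  gc <- Biostrings::GENETIC_CODE
  long <- cmp$long[cmp$long$sample_id == "a" & !is.na(cmp$long$rscu), ]
  sums <- tapply(long$rscu, long$amino_acid, sum)
  sizes <- table(gc[gc != "*"])[names(sums)]
  expect_equal(as.numeric(sums), as.numeric(sizes), tolerance = 1e-9)
})
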