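test_that("n50 matches its definition on worked examples", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)   # cumsum 5, 9 >= 7.5
  expect_equal(n50(100), 100)
  expect_equal(n50(c(10, 10)), 10)
  expect_error(n50(numeric()), class = "txpValidationError")
})

test_that("n50 equals the brute-force oracle on random multisets", {
  set.seed(101)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_identical(n50(lens), bruteN50(lens))
  }
})

test_that("assembly summaries match hand-computed values", {
  tx <- Biostrings::DNAStringSet(c(a = "GGCC", b = "AT"))
  s <- summarizeAssembly(tx)
  expect_equal(s@totalBases, 6)
  expect_equal(s@gcPercent, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(s@meanLength, 3.0)

  one <- summarizeAssembly(Biostrings::DNAStringSet(c(x = "ACGT")))
  expect_equal(one@gcPercent, 50.0)
  expect_equal(one@medianLength, 4)
  expect_equal(one@meanLength, 4)

  three <- summarizeAssembly(Biostrings::DNAStringSet(
    c(a = "AA", b = "ACGT", c = "ACGTAA")))
  expect_equal(three@medianLength, 4)  # even count -> midpoint average
  expect_equal(summarizeAssembly(Biostrings::DNAStringSet(
    c(a = "AC", b = "GGGG")))@medianLength, 3)
})

test_that("GC denominator excludes ambiguity bases", {
  tx <- Biostrings::DNAStringSet(c(a = "GCNN"))
  expect_equal(summarizeAssembly(tx)@gcPercent, 100)
})

test_that("exn50 curve enumerates prefixes correctly", {
  tx <- data.frame(transcript_id = c("a", "b", "c"),
                   length = c(300, 1000, 2000))
  ex <- data.frame(transcript_id = c("a", "b", "c"), tpm = c(90, 9, 1))
  p <- exn50Curve(tx, ex, xs = 90)
  expect_equal(p$exn50, 300)
  expect_equal(p$subset_size, 1L)
  expect_equal(p$min_tpm, 90)
})

test_that("exn50 handles missing expression and zero totals", {
  tx <- data.frame(transcript_id = c("a", "b"), length = c(10, 20))
  ex <- data.frame(transcript_id = "a", tpm = 5)
  expect_warning(p <- exn50Curve(tx, ex, xs = 100), "TPM set to 0")
  expect_equal(p$subset_size, 1L)  # the zero-TPM transcript is not needed
  zero <- data.frame(transcript_id = c("a", "b"), tpm = c(0, 0))
  expect_error(suppressWarnings(exn50Curve(tx, zero, xs = 50)),
               "undefined", class = "txpValidationError")
})

test_that("exn50 curve matches the brute-force oracle on random data", {
  set.seed(77)
  xs <- c(5, 25, 50, 75, 90, 95, 100)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    ids <- sprintf("t%02d", 1:n)
    lens <- sample(100:3000, n, replace = TRUE)
    tpm <- round(rlnorm(n, 2, 2), 3)
    tpm[1] <- tpm[1] + 1  # ensure positive total
    got <- exn50Curve(data.frame(transcript_id = ids, length = lens),
                      data.frame(transcript_id = ids, tpm = tpm), xs = xs)
    want <- bruteExn50(ids, lens, tpm, xs)
    expect_equal(got$exn50, want$exn50)
    expect_equal(got$subset_size, want$subset_size)
    expect_equal(got$min_tpm, want$min_tpm)
  }
})

test_that("exn50 subset size grows and min TPM shrinks along the curve", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    ids <- sprintf("t%02d", 1:n)
    curve <- exn50Curve(
      data.frame(transcript_id = ids,
                 length = sample(100:2000, n, TRUE)),
      data.frame(transcript_id = ids, tpm = rlnorm(n, 1, 2) + 1e-6),
      xs = 1:100)
    expect_true(all(diff(curve$subset_size) >= 0))
    expect_true(all(diff(curve$min_tpm) <= 1e-12))
  }
})

test_that("the full-mass ExN50 equals the plain N50", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    ids <- sprintf("t%02d", 1:n)
    lens <- sample(100:2000, n, TRUE)
    curve <- exn50Curve(data.frame(transcript_id = ids, length = lens),
                        data.frame(transcript_id = ids,
                                   tpm = rlnorm(n, 1, 1.5) + 1e-6),
                        xs = 100)
    expect_equal(curve$exn50, n50(lens))
    expect_equal(curve$subset_size, n)
  }
})

test_that("TPM threshold counting keeps values at the boundary", {
  e <- data.frame(tpm = c(6, 5, 4.9, 0))
  expect_equal(countAboveTpm(e, 5), 2L)
  expect_equal(countAboveTpm(e, 0), 4L)
  expect_equal(countAboveTpm(data.frame(tpm = numeric()), 5), 0L)
  expect_error(countAboveTpm(e, -1), class = "txpValidationError")
  # nonincreasing in the threshold
  thr <- sort(runif(20, 0, 10))
  counts <- vapply(thr, function(t) countAboveTpm(e, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
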