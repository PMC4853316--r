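glyhit <- function(query, subject, evalue = 1e-80, ident = 45,
                   s_start = 1, s_end = 80, subject_length = 100,
                   bitscore = 200) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = ident, aln_length = 80L, mismatches = 0L,
             gap_opens = 0L, q_start = 1L, q_end = 80L,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bitscore = bitscore, subject_length = subject_length)
}

ref2 <- data.frame(gene_id = c("G1", "G2"),
                   category = c("sialyltransferase", "fucosyltransferase"),
                   mechanism = c("inverting", "retaining"),
                   fold = c("GT-A", "unknown"))

test_that("presence calling applies all three thresholds", {
  ok <- glyhit("t1", "G1")  # evalue 1e-80, ident 45, coverage 0.8
  expect_equal(callPresence(ok, ref2)$gene_id, "G1")
  lowcov <- glyhit("t1", "G1", s_end = 30)  # coverage 0.3 < 0.5
  expect_equal(nrow(callPresence(lowcov, ref2)), 0L)
  lowid <- glyhit("t1", "G1", ident = 20)
  expect_equal(nrow(callPresence(lowid, ref2)), 0L)
  weak <- glyhit("t1", "G1", evalue = 1e-10)
  expect_equal(nrow(callPresence(weak, ref2)), 0L)
  expect_equal(nrow(callPresence(glyhit("a", "G1")[0, ], ref2)), 0L)
})

test_that("the max-bitscore passing hit supports the call", {
  hits <- rbind(glyhit("t1", "G1", bitscore = 150),
                glyhit("t2", "G1", bitscore = 250),
                glyhit("t3", "G2", bitscore = 90))
  pres <- callPresence(hits, ref2)
  expect_equal(pres$best_transcript[pres$gene_id == "G1"], "t2")
  expect_equal(pres$best_transcript[pres$gene_id == "G2"], "t3")
})

test_that("hits on unannotated subjects are ignored with a warning", {
  hits <- rbind(glyhit("t1", "G1"), glyhit("t2", "NOVEL"))
  expect_warning(pres <- callPresence(hits, ref2), "absent from")
  expect_equal(pres$gene_id, "G1")
})

test_that("loosening a threshold never removes a present gene", {
  set.seed(17)
  for (i in 1:100) {
    hits <- randomHitTable(nQueries = 8, nHits = 30)
    hits$subject_id <- sample(ref2$gene_id, nrow(hits), replace = TRUE)
    ev <- 10^-runif(1, 0, 60); id <- runif(1, 20, 90); cv <- runif(1)
    strict <- callPresence(hits, ref2, ev, id, cv)
    loose <- callPresence(hits, ref2, ev * 10, id - 5, cv * 0.8)
    expect_true(all(strict$gene_id %in% loose$gene_id))
  }
})

test_that("profiles join presence with expression, one row per gene x sample", {
  pres <- list(
    hv = callPresence(glyhit("t7", "G1"), ref2),
    sf = callPresence(glyhit("t9", "G2"), ref2))
  expr <- list(
    hv = data.frame(transcript_id = "t7", tpm = 33.2),
    sf = data.frame(transcript_id = "t9", tpm = 5))
  prof <- buildProfile(pres, expr, ref2)
  expect_equal(nrow(prof), 2L * nrow(ref2))
  hv1 <- prof[prof$sample_id == "hv" & prof$gene_id == "G1", ]
  expect_true(hv1$present)
  expect_equal(hv1$tpm, 33.2)
  expect_equal(hv1$best_transcript, "t7")
  absent <- prof[prof$sample_id == "hv" & prof$gene_id == "G2", ]
  expect_false(absent$present)
  expect_true(is.na(absent$tpm) && is.na(absent$best_transcript))
  # annotation columns are carried through
  expect_equal(hv1$mechanism, "inverting")
})

test_that("a supporting transcript missing from expression warns", {
  pres <- list(hv = callPresence(glyhit("t7", "G1"), ref2))
  expr <- list(hv = data.frame(transcript_id = "other", tpm = 1))
  expect_warning(prof <- buildProfile(pres, expr, ref2), "missing from")
  expect_true(is.na(prof$tpm[prof$gene_id == "G1"]))
})

test_that("overlap counts are set cardinalities", {
  mk <- function(present) data.frame(gene_id = c("g1", "g2", "g3"),
                                     present = present)
  a <- mk(c(TRUE, TRUE, FALSE)); b <- mk(c(FALSE, TRUE, TRUE))
  ov <- overlapCounts(a, b)
  expect_equal(ov, list(nA = 2L, nB = 2L, nShared = 1L))
  self <- overlapCounts(a, a)
  expect_equal(self$nShared, self$nA)
  disjoint <- overlapCounts(mk(c(TRUE, FALSE, FALSE)),
                            mk(c(FALSE, TRUE, TRUE)))
  expect_equal(disjoint$nShared, 0L)
  expect_lte(ov$nShared, min(ov$nA, ov$nB))
  expect_error(overlapCounts(a, data.frame(gene_id = "x", present = TRUE)),
               class = "txpValidationError")
})

test_that("category counts and mechanism/fold proportions", {
  prof <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    present = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    category = c("a", "a", "b", "c", "d"),
    mechanism = c("inverting", "inverting", "retaining", "unknown",
                  "inverting"),
    fold = c("GT-A", "GT-B", "unknown", "unknown", "GT-A"))
  cc <- categoryCounts(prof)
  expect_equal(cc[["a"]], 2L)
  expect_equal(sum(cc), sum(prof$present))
  expect_false("d" %in% names(cc))
  mf <- mechanismFoldProportions(prof)
  expect_equal(mf$mechanism[["inverting"]], 0.5)
  expect_equal(sum(mf$mechanism), 1, tolerance = 1e-9)
  expect_equal(sum(mf$fold), 1, tolerance = 1e-9)
  allunk <- prof; allunk$mechanism <- "unknown"
  expect_equal(mechanismFoldProportions(allunk)$mechanism[["unknown"]], 1)
  none <- prof; none$present <- FALSE
  expect_length(categoryCounts(none), 0L)
  expect_length(mechanismFoldProportions(none)$mechanism, 0L)
})
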