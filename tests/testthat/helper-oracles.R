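# Independent brute-force oracles. Deliberately naive (explicit loops, no
# code shared with the implementation) so that agreement is meaningful.

bruteN50 <- function(lengths) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

bruteRscu <- function(counts) {
  # counts: named vector over 64 codons; returns named RSCU over the 61
  # sense codons, NA for unobserved families
  gc <- Biostrings::GENETIC_CODE
  out <- c()
  for (aa in setdiff(unique(gc), "*")) {
    fam <- names(gc)[gc == aa]
    total <- 0
    for (cod in fam) total <- total + counts[[cod]]
    for (cod in fam) {
      out[cod] <- if (total == 0) NA_real_
                  else counts[[cod] ] / (total / length(fam))
    }
  }
  out[order(names(out))]
}

bruteExn50 <- function(ids, lengths, tpm, xs) {
  ord <- order(-tpm, -lengths, ids, method = "radix")
  lengths <- lengths[ord]; tpm <- tpm[ord]
  total <- sum(tpm)
  res <- NULL
  for (x in xs) {
    run <- 0; k <- 0
    repeat {
      k <- k + 1
      run <- run + tpm[k]
      if (run >= x / 100 * total || k == length(tpm)) break
    }
    res <- rbind(res, data.frame(x = x,
                                 exn50 = bruteN50(lengths[1:k]),
                                 subset_size = k,
                                 min_tpm = min(tpm[1:k])))
  }
  res
}

bruteBestHit <- function(hits, cutoff) {
  best <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$evalue > cutoff) next
    q <- h$query_id
    cur <- best[[q]]
    if (is.null(cur) ||
        h$bitscore > cur$bitscore ||
        (h$bitscore == cur$bitscore && h$evalue < cur$evalue)) {
      best[[q]] <- h
    }
  }
  best
}

bruteBin <- function(coverages, binWidth) {
  nbin <- 100 / binWidth
  counts <- integer(nbin)
  for (v in coverages) {
    pct <- 100 * v
    for (b in seq_len(nbin)) {
      lo <- (b - 1) * binWidth; hi <- b * binWidth
      inBin <- if (b == 1) pct <= hi else (pct > lo && pct <= hi)
      if (inBin) { counts[b] <- counts[b] + 1; break }
    }
  }
  cum <- integer(nbin)
  for (b in seq_len(nbin)) cum[b] <- sum(counts[b:nbin])
  list(count = counts, cumulative = cum)
}

# random-instance generators used by the property tests
randomCounts <- function() {
  counts <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  n <- sample(3:64, 1)
  picked <- sample(names(counts), n)
  counts[picked] <- sample(0:200, n, replace = TRUE)
  counts
}

makeCountTable <- function(counts, id = "s") {
  new("CodonCountTable", sampleId = id, counts = counts,
      nSequencesUsed = 1L, nSequencesFiltered = 0L,
      nTripletsSkipped = 0L)
}

randomHitTable <- function(nQueries = 5, nHits = 20) {
  q <- sprintf("q%d", sample(nQueries, nHits, replace = TRUE))
  L <- sample(50:500, nHits, replace = TRUE)
  sstart <- sapply(L, function(l) sample(l, 1))
  send <- sapply(L, function(l) sample(l, 1))
  data.frame(
    query_id = q,
    subject_id = sprintf("s%d", sample(10, nHits, replace = TRUE)),
    pct_identity = round(runif(nHits, 20, 100), 1),
    aln_length = abs(send - sstart) + 1L,
    mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = abs(send - sstart) + 1L,
    s_start = sstart, s_end = send,
    # coarse grid so bitscore/evalue ties actually occur
    evalue = 10^-sample(c(5, 25, 50, 80), nHits, replace = TRUE),
    bitscore = sample(seq(40, 400, by = 20), nHits, replace = TRUE),
    subject_length = L
  )
}
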