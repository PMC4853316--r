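#' Count codons over a set of coding sequences
#'
#' Sequences shorter than `minLen` are excluded (and counted as
#' filtered); the default of 300 nt corresponds to a 100 amino-acid
#' protein. Each remaining sequence is presumed an in-frame CDS starting
#' at position 1 and is walked 5' to 3' in non-overlapping triplets; a
#' trailing incomplete triplet is dropped and any triplet containing a
#' non-ACGT character is skipped (and counted).
#'
#' @param cds a `DNAStringSet` (or character vector) of CDS sequences.
#' @param minLen minimum sequence length in nt to be counted (default
#'   300); the filter keeps length `>= minLen`.
#' @param sampleId label stored in the result (default `"sample1"`).
#' @return a [CodonCountTable-class] with all 64 codons zero-filled.
#' @examples
#' cds <- Biostrings::DNAStringSet(c(c1 = "ATGAAAAAATGA"))
#' codonCounts(countCodons(cds, minLen = 0))[c("ATG", "AAA", "TGA")]
#' @export
countCodons <- function(cds, minLen = 300, sampleId = "sample1") {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (length(minLen) != 1L || is.na(minLen) || minLen < 0)
    .txpValidationError("minLen must be a single non-negative number")
  w <- Biostrings::width(cds)
  keep <- w >= minLen
  used <- cds[keep]
  if (!length(used))
    .txpValidationError(sprintf(
      "no sequence is at least %d nt long; lower minLen", as.integer(minLen)))
  w3 <- (Biostrings::width(used) %/% 3L) * 3L
  counts <- setNames(integer(64L), .allCodons())
  skipped <- 0L
  nonempty <- w3 > 0L
  if (any(nonempty)) {
    trimmed <- Biostrings::subseq(used[nonempty], start = 1L,
                                  width = w3[nonempty])
    s <- paste0(as.character(trimmed), collapse = "")
    n <- nchar(s)
    codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    ok <- !grepl("[^ACGT]", codons)
    skipped <- sum(!ok)
    tab <- table(factor(codons[ok], levels = .allCodons()))
    counts[] <- as.integer(tab)
  }
  new("CodonCountTable",
      sampleId = sampleId,
      counts = counts,
      nSequencesUsed = length(used),
      nSequencesFiltered = sum(!keep),
      nTripletsSkipped = as.integer(skipped))
}

#' Relative synonymous codon usage
#'
#' For each amino acid \eqn{i} with synonymous codons
#' \eqn{j = 1, \dots, n_i} and observed counts \eqn{x_{ij}}, the RSCU of
#' codon \eqn{j} is
#' \deqn{RSCU_{ij} = \frac{x_{ij}}{(1/n_i) \sum_j x_{ij}},}
#' the count relative to the family mean. Values of a family therefore
#' always sum to \eqn{n_i} (the family size) when the family was
#' observed; 1 means no bias, and a single-codon amino acid has RSCU 1
#' whenever observed. Amino acids with zero total count get `NA` for all
#' their codons. Stop codons are excluded unless `includeStop` is set, in
#' which case the three stops are treated as one synonymous family.
#'
#' @param counts a [CodonCountTable-class] from [countCodons()].
#' @param includeStop treat the stop codons as a 3-codon family
#'   (default `FALSE`).
#' @return an [RSCUTable-class] object.
#' @examples
#' cds <- Biostrings::DNAStringSet(c(a = "AAAAAAAAGATG"))
#' rscuValues(rscu(countCodons(cds, minLen = 0)))[c("AAA", "AAG", "ATG")]
#' @export
rscu <- function(counts, includeStop = FALSE) {
  stopifnot(is(counts, "CodonCountTable"))
  fams <- .codonFamilies(includeStop)
  x <- codonCounts(counts)
  vals <- unlist(lapply(fams, function(fam) {
    total <- sum(x[fam])
    if (total == 0L) return(setNames(rep(NA_real_, length(fam)), fam))
    setNames(x[fam] / (total / length(fam)), fam)
  }), use.names = TRUE)
  names(vals) <- sub("^[^.]*\\.", "", names(vals))
  new("RSCUTable",
      sampleId = sampleId(counts),
      rscu = vals[order(names(vals))],
      counts = x,
      includeStop = includeStop)
}

#' Per-amino-acid codon bias statistics
#'
#' For each amino acid whose RSCU values are defined, computes the range
#' (max minus min over the synonymous family), the extremes with the
#' codons attaining them, and the population standard deviation (divisor
#' \eqn{n_i}, the family size). A large range means the family is used
#' very unevenly in that sample; the minimum codon is the one an
#' expression construct should avoid. Single-codon amino acids have range
#' and SD 0.
#'
#' @param x an [RSCUTable-class] object.
#' @return a `data.frame` with columns `amino_acid`, `n_codons`,
#'   `rscu_range`, `rscu_min`, `rscu_max`, `rscu_sd`, `min_codon`,
#'   `max_codon`; amino acids with undefined RSCU are omitted. Codon
#'   ties at an extreme resolve to the alphabetically first codon.
#' @export
biasStats <- function(x) {
  stopifnot(is(x, "RSCUTable"))
  fams <- .codonFamilies(x@includeStop)
  v <- rscuValues(x)
  rows <- lapply(names(fams), function(aa) {
    fam <- sort(fams[[aa]])
    vals <- v[fam]
    if (all(is.na(vals))) return(NULL)
    mu <- mean(vals)
    data.frame(
      amino_acid = aa,
      n_codons = length(fam),
      rscu_range = max(vals) - min(vals),
      rscu_min = min(vals),
      rscu_max = max(vals),
      rscu_sd = sqrt(mean((vals - mu)^2)),
      min_codon = fam[which.min(vals)],
      max_codon = fam[which.max(vals)]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare RSCU across samples or species
#'
#' Aligns several [RSCUTable-class] objects on their common codon set and
#' returns codon-by-sample RSCU matrices plus per-amino-acid range and
#' population-SD matrices, the cross-species view of codon bias. Samples
#' with low range/SD values across amino acids use their synonymous
#' codons homogeneously, a favourable property in an expression host.
#'
#' @param tables list of [RSCUTable-class] objects with distinct sample
#'   ids and the same stop-codon treatment.
#' @return a list with elements `rscu` (codon x sample matrix), `range`
#'   and `sd` (amino acid x sample matrices) and `long` (a long-format
#'   `data.frame` with columns `sample_id`, `codon`, `amino_acid`,
#'   `count`, `rscu`).
#' @export
compareSamples <- function(tables) {
  if (!length(tables))
    .txpValidationError("need at least one RSCU table")
  stopifnot(all(vapply(tables, is, logical(1L), "RSCUTable")))
  ids <- vapply(tables, sampleId, character(1L))
  if (anyDuplicated(ids))
    .txpValidationError(sprintf("duplicate sample id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  incl <- vapply(tables, function(t) t@includeStop, logical(1L))
  if (length(unique(incl)) != 1L)
    .txpValidationError("tables mix stop-codon treatments")
  codons <- sort(names(rscuValues(tables[[1L]])))
  gc <- .geneticCode()
  m <- vapply(tables, function(t) rscuValues(t)[codons],
              numeric(length(codons)))
  colnames(m) <- ids
  stats <- lapply(tables, biasStats)
  aas <- sort(unique(unlist(lapply(stats, `[[`, "amino_acid"))))
  pick <- function(col) {
    out <- vapply(stats, function(s)
      s[[col]][match(aas, s$amino_acid)], numeric(length(aas)))
    out <- matrix(out, nrow = length(aas),
                  dimnames = list(aas, ids))
    out
  }
  long <- do.call(rbind, lapply(tables, function(t) {
    data.frame(sample_id = sampleId(t), codon = codons,
               amino_acid = unname(gc[codons]),
               count = unname(codonCounts(t)[codons]),
               rscu = unname(rscuValues(t)[codons]))
  }))
  rownames(long) <- NULL
  list(rscu = m, range = pick("rscu_range"), sd = pick("rscu_sd"),
       long = long)
}
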