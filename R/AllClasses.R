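#' Codon counts over a set of coding sequences
#'
#' Holds the 64-codon count vector obtained by walking each CDS 5' to 3' in
#' non-overlapping triplets, together with bookkeeping on how many sequences
#' passed the minimum-length filter. The genetic code is fixed to the
#' standard (NCBI table 1) code.
#'
#' @slot sampleId single character, the sample/species label.
#' @slot counts named integer vector over all 64 codons (zero-filled).
#' @slot nSequencesUsed number of sequences that contributed codons.
#' @slot nSequencesFiltered number of sequences removed by the length filter.
#' @slot nTripletsSkipped triplets skipped because they contained a
#'   non-ACGT character.
#'
#' @seealso [countCodons()], [rscu()]
#' @export
setClass("CodonCountTable",
  representation(
    sampleId = "character",
    counts = "integer",
    nSequencesUsed = "integer",
    nSequencesFiltered = "integer",
    nTripletsSkipped = "integer"
  )
)

setValidity("CodonCountTable", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  codons <- .allCodons()
  if (length(object@counts) != 64L ||
      !identical(sort(names(object@counts)), sort(codons)))
    msg <- c(msg, "counts must be named over all 64 codons")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Relative synonymous codon usage (RSCU) for one sample
#'
#' RSCU of codon \eqn{j} within the synonymous family of amino acid
#' \eqn{i} is \eqn{x_{ij} / ((1/n_i) \sum_j x_{ij})}: the observed count
#' divided by the mean count over the family. Values for an amino acid
#' whose family was never observed are `NA` (the formula is 0/0 there).
#' The backing counts are retained so the family totals \eqn{\sum_j x_{ij}}
#' and sizes \eqn{n_i} remain available.
#'
#' @slot sampleId single character, the sample/species label.
#' @slot rscu named numeric vector over the codons considered (61 sense
#'   codons, plus the 3 stop codons when `includeStop` was set).
#' @slot counts the backing codon counts (all 64 codons).
#' @slot includeStop whether stop codons were treated as a synonymous family.
#'
#' @seealso [rscu()], [biasStats()], [compareSamples()]
#' @export
setClass("RSCUTable",
  representation(
    sampleId = "character",
    rscu = "numeric",
    counts = "integer",
    includeStop = "logical"
  )
)

setValidity("RSCUTable", function(object) {
  msg <- character()
  fams <- .codonFamilies(object@includeStop)
  expected <- sort(unlist(fams, use.names = FALSE))
  if (!identical(sort(names(object@rscu)), expected))
    msg <- c(msg, "rscu must be named over the codons under consideration")
  # the defining invariant: family RSCU values sum to the family size
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    total <- sum(object@counts[fam])
    vals <- object@rscu[fam]
    if (total > 0L) {
      if (anyNA(vals) || abs(sum(vals) - length(fam)) > 1e-9)
        msg <- c(msg, sprintf(
          "RSCU values for amino acid '%s' must sum to %d", aa, length(fam)))
    } else if (!all(is.na(vals))) {
      msg <- c(msg, sprintf(
        "amino acid '%s' was never observed; its RSCU must be NA", aa))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Length/GC summary of an assembly
#'
#' @slot nTranscripts number of transcripts.
#' @slot totalBases total assembled bases (bp).
#' @slot gcPercent G+C percentage of non-ambiguous bases, 0-100.
#' @slot medianLength,meanLength median and mean transcript length (bp).
#' @slot n50 assembly N50 (bp).
#'
#' @seealso [summarizeAssembly()], [n50()]
#' @export
setClass("AssemblySummary",
  representation(
    nTranscripts = "integer",
    totalBases = "numeric",
    gcPercent = "numeric",
    medianLength = "numeric",
    meanLength = "numeric",
    n50 = "numeric"
  )
)

setValidity("AssemblySummary", function(object) {
  msg <- character()
  if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
  if (object@gcPercent < 0 || object@gcPercent > 100)
    msg <- c(msg, "gcPercent must lie in [0, 100]")
  if (object@totalBases < object@nTranscripts)
    msg <- c(msg, "totalBases must be at least nTranscripts")
  if (length(msg)) msg else TRUE
})
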