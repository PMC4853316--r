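#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("codonCounts", function(object) standardGeneric("codonCounts"))

#' @rdname accessors
#' @export
setGeneric("rscuValues", function(object) standardGeneric("rscuValues"))

#' @rdname accessors
#' @export
setGeneric("nSequencesUsed",
           function(object) standardGeneric("nSequencesUsed"))

#' @rdname accessors
#' @export
setGeneric("nSequencesFiltered",
           function(object) standardGeneric("nSequencesFiltered"))

#' Accessors for codon-usage and assembly-summary objects
#'
#' `sampleId()` returns the sample label; `codonCounts()` the named
#' 64-codon count vector; `rscuValues()` the named RSCU vector;
#' `nSequencesUsed()` / `nSequencesFiltered()` the length-filter
#' bookkeeping of [countCodons()].
#'
#' @param object a [CodonCountTable-class] or [RSCUTable-class] object.
#' @return see each accessor's description.
#' @examples
#' cds <- Biostrings::DNAStringSet(c(c1 = "ATGAAAAAATGA"))
#' ct <- countCodons(cds, minLen = 0)
#' sampleId(ct)
#' codonCounts(ct)[c("ATG", "AAA", "TGA")]
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleId", "CodonCountTable", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "RSCUTable", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("codonCounts", "CodonCountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("codonCounts", "RSCUTable", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("rscuValues", "RSCUTable", function(object) object@rscu)

#' @rdname accessors
#' @export
setMethod("nSequencesUsed", "CodonCountTable",
          function(object) object@nSequencesUsed)

#' @rdname accessors
#' @export
setMethod("nSequencesFiltered", "CodonCountTable",
          function(object) object@nSequencesFiltered)

setMethod("show", "CodonCountTable", function(object) {
  cat("CodonCountTable for sample '", object@sampleId, "'\n", sep = "")
  cat("  total codons counted: ", sum(object@counts), "\n", sep = "")
  cat("  sequences used: ", object@nSequencesUsed,
      " (", object@nSequencesFiltered, " removed by length filter)\n",
      sep = "")
  if (object@nTripletsSkipped > 0L)
    cat("  triplets skipped (ambiguous bases): ",
        object@nTripletsSkipped, "\n", sep = "")
  top <- sort(object@counts, decreasing = TRUE)[1:5]
  cat("  most frequent codons: ",
      paste(names(top), top, sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "RSCUTable", function(object) {
  cat("RSCUTable for sample '", object@sampleId, "'",
      if (object@includeStop) " (stop codons included)", "\n", sep = "")
  v <- object@rscu[!is.na(object@rscu)]
  cat("  codons with defined RSCU: ", length(v), "/",
      length(object@rscu), "\n", sep = "")
  if (length(v)) {
    cat("  RSCU range: [", sprintf("%.3f", min(v)), ", ",
        sprintf("%.3f", max(v)), "]\n", sep = "")
  }
})

setMethod("show", "AssemblySummary", function(object) {
  cat("AssemblySummary\n")
  cat(sprintf("  transcripts:          %d\n", object@nTranscripts))
  cat(sprintf("  total bases (bp):     %.0f\n", object@totalBases))
  cat(sprintf("  GC content (%%):       %.2f\n", object@gcPercent))
  cat(sprintf("  median length (bp):   %.1f\n", object@medianLength))
  cat(sprintf("  mean length (bp):     %.1f\n", object@meanLength))
  cat(sprintf("  N50 (bp):             %.0f\n", object@n50))
})

#' Coerce an AssemblySummary to a one-row data.frame
#'
#' @param x an [AssemblySummary-class] object.
#' @param ... unused.
#' @return a one-row `data.frame` with columns `n_transcripts`,
#'   `total_bases`, `gc_percent`, `median_length`, `mean_length`, `n50`.
#' @export
as.data.frame.AssemblySummary <- function(x, ...) {
  data.frame(
    n_transcripts = x@nTranscripts,
    total_bases = x@totalBases,
    gc_percent = x@gcPercent,
    median_length = x@medianLength,
    mean_length = x@meanLength,
    n50 = x@n50
  )
}
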