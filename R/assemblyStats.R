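#' Assembly N50
#'
#' The N50 is the length \eqn{L} such that transcripts of length at least
#' \eqn{L}, taken from the longest downwards, contain at least half of the
#' total assembled bases. Computed by sorting lengths in decreasing order
#' and returning the length at which the running sum first reaches half
#' the total; the result is always one of the observed lengths.
#'
#' @param lengths positive integer vector of transcript lengths (bp).
#' @return the N50 length in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # total 15; cumulative 5, 9 >= 7.5 -> 4
#' @export
n50 <- function(lengths) {
  if (!length(lengths))
    .txpValidationError("cannot compute N50 of an empty length set")
  if (anyNA(lengths) || any(lengths < 1))
    .txpValidationError("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Summary statistics of an assembly
#'
#' Computes transcript count, total assembled bases, pooled GC percentage,
#' median and mean length and N50. GC is taken over all sequences jointly,
#' with N/ambiguity bases excluded from both numerator and denominator
#' (GC of the known bases). The median of an even-sized set is the mean of
#' the two central values.
#'
#' @param transcripts a `DNAStringSet` of assembled transcripts.
#' @return an [AssemblySummary-class] object.
#' @examples
#' tx <- Biostrings::DNAStringSet(c(a = "GGCC", b = "AT"))
#' summarizeAssembly(tx)
#' @export
summarizeAssembly <- function(transcripts) {
  if (!length(transcripts))
    .txpValidationError("cannot summarize an empty assembly")
  lens <- Biostrings::width(transcripts)
  freq <- Biostrings::alphabetFrequency(transcripts, collapse = TRUE)
  gc <- sum(freq[c("G", "C")])
  acgt <- sum(freq[c("A", "C", "G", "T")])
  if (acgt == 0)
    .txpValidationError("no unambiguous A/C/G/T bases in the assembly")
  new("AssemblySummary",
      nTranscripts = length(transcripts),
      totalBases = sum(as.numeric(lens)),
      gcPercent = 100 * gc / acgt,
      medianLength = as.numeric(median(lens)),
      meanLength = sum(as.numeric(lens)) / length(lens),
      n50 = as.numeric(n50(lens)))
}

#' Expression-weighted ExN50 curve
#'
#' For each percentage `x`, the Ex subset is the smallest set of most
#' highly expressed transcripts whose cumulative TPM reaches `x` percent
#' of the total TPM mass, and ExN50 is the N50 of that subset's lengths.
#' Transcripts are ordered by TPM descending with deterministic
#' tie-breaking (length descending, then id ascending) so the curve is
#' bit-reproducible. Transcripts without an expression record are treated
#' as TPM 0 with a warning.
#'
#' @param transcripts a `DNAStringSet`, or a `data.frame` with columns
#'   `transcript_id` and `length`.
#' @param expression expression `data.frame` as returned by
#'   [readExpressionTable()].
#' @param xs integer percentages to evaluate (default `1:100`).
#' @return a `data.frame` with columns `x`, `exn50`, `subset_size`,
#'   `min_tpm` (the smallest TPM inside the Ex subset).
#' @examples
#' tx <- data.frame(transcript_id = c("a", "b", "c"),
#'                  length = c(300, 1000, 2000))
#' ex <- data.frame(transcript_id = c("a", "b", "c"), tpm = c(90, 9, 1))
#' exn50Curve(tx, ex, xs = c(90, 100))
#' @export
exn50Curve <- function(transcripts, expression, xs = 1:100) {
  tab <- .transcriptLengths(transcripts)
  if (any(xs < 1 | xs > 100))
    .txpValidationError("xs must be percentages in [1, 100]")
  tpm <- expression$tpm[match(tab$transcript_id, expression$transcript_id)]
  if (anyNA(tpm)) {
    warning(sum(is.na(tpm)),
            " transcript(s) without an expression record; TPM set to 0")
    tpm[is.na(tpm)] <- 0
  }
  total <- sum(tpm)
  if (total <= 0)
    .txpValidationError("total TPM is zero; ExN50 curve is undefined")
  ord <- order(-tpm, -tab$length, tab$transcript_id, method = "radix")
  tpm <- tpm[ord]
  len <- tab$length[ord]
  ctpm <- cumsum(tpm)
  res <- lapply(xs, function(x) {
    k <- which(ctpm >= x / 100 * total)[1L]
    if (is.na(k)) k <- length(ctpm)  # x = 100 under rounding
    data.frame(x = x, exn50 = as.numeric(n50(len[seq_len(k)])),
               subset_size = k, min_tpm = tpm[k])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.transcriptLengths <- function(transcripts) {
  if (is.data.frame(transcripts)) {
    if (!all(c("transcript_id", "length") %in% colnames(transcripts)))
      .txpValidationError(
        "transcripts data.frame needs columns transcript_id and length")
    data.frame(transcript_id = as.character(transcripts$transcript_id),
               length = as.numeric(transcripts$length))
  } else {
    data.frame(transcript_id = .fastaIds(names(transcripts)),
               length = as.numeric(Biostrings::width(transcripts)))
  }
}

#' Count transcripts at or above a TPM threshold
#'
#' Counts expression records with TPM greater than or equal to the
#' threshold: filtering "below 5" keeps exactly the records with
#' TPM >= 5.
#'
#' @param expression expression `data.frame` (needs a `tpm` column).
#' @param threshold non-negative TPM threshold.
#' @return the number of records kept.
#' @examples
#' countAboveTpm(data.frame(tpm = c(6, 5, 4.9, 0)), 5)  # 2
#' @export
countAboveTpm <- function(expression, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    .txpValidationError("threshold must be a single non-negative number")
  sum(expression$tpm >= threshold)
}
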