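#' Best alignment hit per query
#'
#' Discards hits above the e-value cutoff (comparison is inclusive,
#' `evalue <= cutoff`) and keeps, for each query, the hit with the highest
#' bitscore; ties are broken by the smaller e-value, then by first
#' occurrence in the table.
#'
#' @param hits hit `data.frame` as returned by [readTabularHits()].
#' @param evalueCutoff e-value cutoff (default `1e-20`).
#' @return a `data.frame` with one row per surviving query, in order of
#'   each query's first appearance.
#' @export
bestHitPerQuery <- function(hits, evalueCutoff = 1e-20) {
  if (length(evalueCutoff) != 1L || is.na(evalueCutoff) || evalueCutoff < 0)
    .txpValidationError("evalueCutoff must be a single non-negative number")
  keep <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  keep$.row <- seq_len(nrow(keep))
  ord <- order(-keep$bitscore, keep$evalue, keep$.row, method = "radix")
  keep <- keep[ord, , drop = FALSE]
  best <- keep[!duplicated(keep$query_id), , drop = FALSE]
  # present queries in order of first appearance in the input
  first <- tapply(keep$.row, keep$query_id, min)
  best <- best[order(first[best$query_id]), , drop = FALSE]
  best$.row <- NULL
  rownames(best) <- NULL
  best
}

#' Subject coverage of alignment hits
#'
#' The fraction of the subject (homolog) protein spanned by the aligned
#' subject coordinates: `(|s_end - s_start| + 1) / subject_length`,
#' clamped to at most 1. The subject-coordinate span is used rather than
#' the alignment-length column, which counts gap columns and can exceed
#' the subject span. Coordinates are 1-based inclusive and may be given
#' in either orientation.
#'
#' @param hits hit `data.frame` (one or more rows).
#' @return numeric vector of coverage fractions in (0, 1], one per row.
#' @examples
#' h <- data.frame(s_start = 1, s_end = 50, subject_length = 100)
#' subjectCoverage(h)  # 0.5
#' @export
subjectCoverage <- function(hits) {
  if (is.null(hits$subject_length) || anyNA(hits$subject_length))
    .txpValidationError("subject_length is required to compute coverage")
  if (any(hits$subject_length < 1))
    .txpValidationError("subject_length must be positive")
  span <- abs(hits$s_end - hits$s_start) + 1
  pmin(span / hits$subject_length, 1)
}

#' Bin coverage fractions with cumulative counts
#'
#' Assigns each coverage value to a half-open percentage bin
#' `(lower, upper]` of width `binWidth` (top bin closed; an exact 0 falls
#' in the lowest bin) and computes the cumulative count from the 100
#' percent bin downwards, i.e. `cumulative` at a bin is the number of
#' values strictly above its lower bound.
#'
#' @param coverages numeric vector of fractions in `[0, 1]`.
#' @param binWidth bin width in percent; must divide 100 (default 10).
#' @return a `data.frame` with columns `lower`, `upper`, `count`,
#'   `cumulative`, ordered from the lowest bin upwards.
#' @examples
#' binCoverage(c(0.05, 0.5, 0.95, 1.0))
#' @export
binCoverage <- function(coverages, binWidth = 10) {
  if (length(binWidth) != 1L || is.na(binWidth) || binWidth <= 0 ||
      100 %% binWidth != 0)
    .txpValidationError("binWidth must divide 100")
  if (length(coverages) && (anyNA(coverages) ||
      any(coverages < 0 | coverages > 1)))
    .txpValidationError("coverage fractions must lie in [0, 1]")
  nbin <- as.integer(100 / binWidth)
  lower <- binWidth * (seq_len(nbin) - 1L)
  upper <- binWidth * seq_len(nbin)
  pct <- 100 * coverages
  idx <- ceiling(pct / binWidth)
  idx[idx < 1L] <- 1L  # exact zero goes to the lowest bin
  counts <- tabulate(idx, nbins = nbin)
  data.frame(
    lower = lower, upper = upper, count = counts,
    cumulative = rev(cumsum(rev(counts)))
  )
}
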