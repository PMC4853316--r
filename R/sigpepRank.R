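#' Rank predicted signal peptides by transcript expression
#'
#' Joins signal-positive predictions to their source transcript's TPM and
#' sorts by TPM descending (ties: D-score descending, then protein id
#' ascending). The signal sequence is the protein's residues 1 to
#' `cleavage_pos - 1` (the predictor reports the first residue of the
#' mature protein). Predictions whose protein does not begin with
#' methionine are flagged as possibly 5'-truncated — the assembled
#' transcript may miss the true start, so the predicted signal deserves
#' manual review — but are never removed.
#'
#' @param predictions `data.frame` from [readSignalp()]; only
#'   `is_signal = TRUE` rows are considered.
#' @param expression expression `data.frame`; a prediction whose
#'   transcript has no expression row is kept at TPM 0 with a warning.
#' @param proteins an `AAStringSet` of the predicted proteins.
#' @param idMap named character vector mapping protein id to transcript
#'   id, or a two-column `data.frame` (protein_id, transcript_id).
#'   Defaults to the identity map.
#' @return a `data.frame` with columns `rank` (1..k), `transcript_id`,
#'   `protein_id`, `tpm`, `d_score`, `signal_sequence`,
#'   `truncation_flag`, sorted by TPM descending.
#' @export
rankSignalPeptides <- function(predictions, expression, proteins,
                               idMap = NULL) {
  if (is.data.frame(idMap))
    idMap <- setNames(as.character(idMap[[2L]]), as.character(idMap[[1L]]))
  sig <- predictions[predictions$is_signal, , drop = FALSE]
  if (!nrow(sig)) return(.emptyRanked())
  pid <- .fastaIds(names(proteins))
  pidx <- match(sig$protein_id, pid)
  if (anyNA(pidx))
    .txpValidationError(sprintf(
      "protein sequence missing for prediction '%s'",
      sig$protein_id[which(is.na(pidx))[1L]]))
  tx <- if (is.null(idMap)) sig$protein_id else unname(idMap[sig$protein_id])
  drop <- is.na(tx)
  if (any(drop)) {
    warning(sum(drop), " prediction(s) with no transcript mapping dropped")
    sig <- sig[!drop, , drop = FALSE]
    pidx <- pidx[!drop]
    tx <- tx[!drop]
  }
  if (!nrow(sig)) return(.emptyRanked())
  tpm <- expression$tpm[match(tx, expression$transcript_id)]
  if (anyNA(tpm)) {
    warning(sum(is.na(tpm)),
            " prediction(s) without an expression record; TPM set to 0")
    tpm[is.na(tpm)] <- 0
  }
  plen <- Biostrings::width(proteins)[pidx]
  over <- sig$cleavage_pos > plen
  if (any(over))
    .txpValidationError(sprintf(
      "cleavage position %d of '%s' exceeds its protein length %d",
      sig$cleavage_pos[which(over)[1L]], sig$protein_id[which(over)[1L]],
      plen[which(over)[1L]]))
  seqs <- as.character(Biostrings::subseq(proteins[pidx], start = 1L,
                                          width = sig$cleavage_pos - 1L))
  ord <- order(-tpm, -sig$d_score, sig$protein_id, method = "radix")
  out <- data.frame(
    rank = seq_along(ord),
    transcript_id = tx[ord],
    protein_id = sig$protein_id[ord],
    tpm = tpm[ord],
    d_score = sig$d_score[ord],
    signal_sequence = unname(seqs[ord]),
    truncation_flag = !startsWith(unname(seqs[ord]), "M")
  )
  rownames(out) <- NULL
  out
}

.emptyRanked <- function() {
  data.frame(rank = integer(), transcript_id = character(),
             protein_id = character(), tpm = numeric(),
             d_score = numeric(), signal_sequence = character(),
             truncation_flag = logical())
}

#' Top-N ranked signal peptides
#'
#' @param ranked output of [rankSignalPeptides()].
#' @param n number of entries to keep (default 100); shorter inputs are
#'   returned whole.
#' @return the first `min(n, nrow(ranked))` rows, ranks preserved.
#' @export
topN <- function(ranked, n = 100) {
  if (length(n) != 1L || is.na(n) || n <= 0)
    .txpValidationError("n must be a single positive number")
  head(ranked, n)
}
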