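#' Call glycogene presence from homology hits
#'
#' A reference glycogene is called present in a sample when at least one
#' hit of the sample's proteins against that gene passes all three
#' thresholds: e-value at most `evalueCutoff`, percent identity at least
#' `minIdentity`, and subject coverage (fraction of the reference
#' protein's residues spanned, see [subjectCoverage()]) at least
#' `minSubjectCoverage`. The passing hit with the highest bitscore is
#' recorded as the supporting evidence. Published catalogues of this kind
#' are typically finished by manual curation; the thresholds here are an
#' explicit, reproducible stand-in for that step.
#'
#' @param hits hit `data.frame` (queries are sample proteins/transcripts,
#'   subjects are reference glycogenes).
#' @param annotations glycogene reference `data.frame` from
#'   [readGlycoReference()]; hits on subjects absent from it are dropped
#'   with a warning.
#' @param evalueCutoff,minIdentity,minSubjectCoverage thresholds
#'   (defaults `1e-20`, 30 percent identity, 0.5 coverage).
#' @return a `data.frame` with one row per present gene: `gene_id`,
#'   `best_transcript` (the query id of the supporting hit), `bitscore`,
#'   `evalue`, `pct_identity`, `subject_coverage`.
#' @export
callPresence <- function(hits, annotations, evalueCutoff = 1e-20,
                         minIdentity = 30, minSubjectCoverage = 0.5) {
  known <- hits$subject_id %in% annotations$gene_id
  if (any(!known)) {
    warning(sum(!known), " hit(s) on subjects absent from the ",
            "glycogene reference were ignored")
    hits <- hits[known, , drop = FALSE]
  }
  empty <- data.frame(gene_id = character(), best_transcript = character(),
                      bitscore = numeric(), evalue = numeric(),
                      pct_identity = numeric(), subject_coverage = numeric())
  if (!nrow(hits)) return(empty)
  cov <- subjectCoverage(hits)
  pass <- hits$evalue <= evalueCutoff & hits$pct_identity >= minIdentity &
    cov >= minSubjectCoverage
  hits <- hits[pass, , drop = FALSE]
  cov <- cov[pass]
  if (!nrow(hits)) return(empty)
  ord <- order(-hits$bitscore, hits$evalue, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  cov <- cov[ord]
  best <- !duplicated(hits$subject_id)
  out <- data.frame(
    gene_id = hits$subject_id[best],
    best_transcript = hits$query_id[best],
    bitscore = hits$bitscore[best],
    evalue = hits$evalue[best],
    pct_identity = hits$pct_identity[best],
    subject_coverage = cov[best]
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a glycogene presence/expression profile
#'
#' One row per reference gene and sample, recording presence, the best
#' supporting transcript and its TPM (the expression of a gene is that of
#' its single best supporting transcript, giving one expression mark per
#' gene).
#'
#' @param presence named list of per-sample presence calls from
#'   [callPresence()]; names are sample ids.
#' @param expression named list of per-sample expression `data.frame`s
#'   (same names); a supporting transcript missing from its table leaves
#'   `tpm` as `NA` with a warning.
#' @param annotations glycogene reference `data.frame`.
#' @return a `data.frame` with columns `gene_id`, `sample_id`, `present`,
#'   `best_transcript`, `tpm`, `category`, `mechanism`, `fold`, with
#'   `nrow = nrow(annotations) * length(presence)`.
#' @export
buildProfile <- function(presence, expression, annotations) {
  if (is.null(names(presence)) || any(!nzchar(names(presence))))
    .txpValidationError("presence must be a named list (sample ids)")
  if (!all(names(presence) %in% names(expression)))
    .txpValidationError("every presence sample needs an expression table")
  rows <- lapply(names(presence), function(sid) {
    pres <- presence[[sid]]
    expr <- expression[[sid]]
    i <- match(annotations$gene_id, pres$gene_id)
    best <- pres$best_transcript[i]
    tpm <- expr$tpm[match(best, expr$transcript_id)]
    lost <- !is.na(best) & is.na(tpm)
    if (any(lost))
      warning(sum(lost), " supporting transcript(s) of sample '", sid,
              "' missing from its expression table; TPM left NA")
    data.frame(
      gene_id = annotations$gene_id,
      sample_id = sid,
      present = !is.na(i),
      best_transcript = best,
      tpm = tpm,
      category = annotations$category,
      mechanism = annotations$mechanism,
      fold = annotations$fold
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of present glycogenes between two samples
#'
#' @param profileA,profileB single-sample profile `data.frame`s (rows of
#'   [buildProfile()] output for one sample each) over the same
#'   reference.
#' @return a list with `nA`, `nB` (present-gene counts) and `nShared`
#'   (genes present in both).
#' @export
overlapCounts <- function(profileA, profileB) {
  if (!setequal(profileA$gene_id, profileB$gene_id))
    .txpValidationError("profiles cover different glycogene references")
  a <- profileA$gene_id[profileA$present]
  b <- profileB$gene_id[profileB$present]
  list(nA = length(a), nB = length(b),
       nShared = length(intersect(a, b)))
}

#' Category counts of present glycogenes
#'
#' @param profile profile `data.frame` rows (typically one sample).
#' @return named integer vector: present-gene count per category
#'   (empty when nothing is present).
#' @export
categoryCounts <- function(profile) {
  pres <- profile[profile$present, , drop = FALSE]
  if (!nrow(pres)) return(setNames(integer(), character()))
  tab <- table(pres$category)
  setNames(as.integer(tab), names(tab))
}

#' Mechanism and fold proportions of present glycogenes
#'
#' Proportions of the catalytic mechanism (`inverting` / `retaining` /
#' `unknown`) and of the structural fold (`GT-A` / `GT-B` / `unknown`)
#' among present genes; each axis sums to 1.
#'
#' @param profile profile `data.frame` rows (typically one sample).
#' @return a list with numeric vectors `mechanism` and `fold`, or both
#'   empty when no gene is present (proportions undefined).
#' @export
mechanismFoldProportions <- function(profile) {
  pres <- profile[profile$present, , drop = FALSE]
  if (!nrow(pres))
    return(list(mechanism = setNames(numeric(), character()),
                fold = setNames(numeric(), character())))
  prop <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    setNames(as.numeric(tab) / length(x), levels)
  }
  list(mechanism = prop(pres$mechanism, .glycoMechanisms),
       fold = prop(pres$fold, .glycoFolds))
}
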