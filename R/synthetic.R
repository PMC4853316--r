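#' Specification for the synthetic test corpus
#'
#' Collects every parameter of the seeded generators in one object.
#' Defaults describe a small but realistically shaped corpus: CDS lengths
#' log-normal around 900 nt (floored at 90 nt and rounded to codons),
#' moderately biased codon usage (Dirichlet concentration 1), a
#' heavy-tailed TPM distribution (log-normal, sdlog 2) normalized to one
#' million, subject coverages Beta(2, 1.5) so most hits span over half of
#' their homolog, a 15 percent secretome and signal peptides of 15-30
#' residues.
#'
#' A single master seed is fanned out deterministically to per-generator
#' child seeds, so each generator is reproducible on its own and the full
#' corpus is byte-identical across runs.
#'
#' @param seed master seed (integer).
#' @param nCds number of coding sequences.
#' @param lengthMeanLog,lengthSdLog log-normal parameters of the CDS
#'   length distribution (nt).
#' @param lengthMin minimum CDS length in nt (rounded up to a codon
#'   multiple).
#' @param codonAlpha Dirichlet concentration for the within-amino-acid
#'   codon probabilities; smaller values give stronger bias.
#' @param tpmMeanLog,tpmSdLog log-normal parameters of the unnormalized
#'   expression draws.
#' @param coverageShape1,coverageShape2 Beta parameters of the
#'   subject-coverage distribution.
#' @param pSignal probability that a protein carries a signal peptide.
#' @param signalLengthRange integer range (min, max) of signal peptide
#'   lengths in residues.
#' @return an object of class `"SyntheticSpec"` (a validated list).
#' @examples
#' spec <- syntheticSpec(seed = 42, nCds = 50)
#' profile <- makeCodonProfile(spec)
#' cds <- generateCds(profile, spec)
#' @export
syntheticSpec <- function(seed = 1L, nCds = 300L,
                          lengthMeanLog = log(900), lengthSdLog = 0.6,
                          lengthMin = 90L, codonAlpha = 1,
                          tpmMeanLog = 0, tpmSdLog = 2,
                          coverageShape1 = 2, coverageShape2 = 1.5,
                          pSignal = 0.15,
                          signalLengthRange = c(15L, 30L)) {
  spec <- list(seed = as.integer(seed), nCds = as.integer(nCds),
               lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
               lengthMin = as.integer(lengthMin), codonAlpha = codonAlpha,
               tpmMeanLog = tpmMeanLog, tpmSdLog = tpmSdLog,
               coverageShape1 = coverageShape1,
               coverageShape2 = coverageShape2,
               pSignal = pSignal,
               signalLengthRange = as.integer(signalLengthRange))
  if (spec$nCds < 1L) .txpValidationError("nCds must be positive")
  if (spec$codonAlpha <= 0)
    .txpValidationError("codonAlpha must be positive")
  if (spec$lengthMin < 9L)
    .txpValidationError("lengthMin must allow at least 3 codons")
  if (spec$pSignal < 0 || spec$pSignal > 1)
    .txpValidationError("pSignal must lie in [0, 1]")
  if (length(spec$signalLengthRange) != 2L ||
      spec$signalLengthRange[1L] > spec$signalLengthRange[2L] ||
      spec$signalLengthRange[1L] < 1L)
    .txpValidationError("signalLengthRange must be a valid integer range")
  if (spec$coverageShape1 <= 0 || spec$coverageShape2 <= 0)
    .txpValidationError("coverage Beta parameters must be positive")
  structure(spec, class = "SyntheticSpec")
}

# deterministic fan-out of the master seed; offsets are per generator
.childSeed <- function(spec, offset) {
  as.integer((1103515245 * (as.double(spec$seed) + offset) + 12345) %%
               2147483647)
}

#' Per-amino-acid codon probability profile
#'
#' Draws, for every amino acid, a probability vector over its synonymous
#' codons from a symmetric Dirichlet with concentration
#' `spec$codonAlpha` (realized as normalized gamma draws). These are the
#' ground-truth probabilities `p` that the RSCU of the generated CDS
#' converges to (`RSCU -> n_i * p_j`).
#'
#' @param spec a [syntheticSpec()] object.
#' @return named list (by amino-acid letter, stops under `"*"`) of named
#'   probability vectors, each summing to 1.
#' @export
makeCodonProfile <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(.childSeed(spec, 1L))
  fams <- .codonFamilies(includeStop = TRUE)
  lapply(fams, function(fam) {
    g <- rgamma(length(fam), shape = spec$codonAlpha, rate = 1)
    # guard against all-zero underflow at tiny alpha
    if (sum(g) == 0) g <- rep(1, length(fam))
    setNames(g / sum(g), fam)
  })
}

#' Generate in-frame coding sequences
#'
#' Each CDS starts with ATG, ends with a single stop codon and has a body
#' of amino acids drawn i.i.d. uniformly over the 20 standard residues,
#' with each residue's codon drawn from the profile. Lengths are
#' log-normal, rounded to codon multiples and floored at
#' `spec$lengthMin`. No internal stop codons occur by construction.
#'
#' @param profile output of [makeCodonProfile()].
#' @param spec a [syntheticSpec()] object.
#' @param ids optional sequence ids (default `t000001`...).
#' @return a named `DNAStringSet` of length `spec$nCds`.
#' @export
generateCds <- function(profile, spec, ids = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(.childSeed(spec, 2L))
  n <- spec$nCds
  if (is.null(ids)) ids <- sprintf("t%06d", seq_len(n))
  minCodons <- ceiling(spec$lengthMin / 3)
  nCodons <- pmax(round(rlnorm(n, spec$lengthMeanLog,
                               spec$lengthSdLog) / 3), minCodons)
  aaLetters <- setdiff(names(profile), "*")
  bodyLens <- nCodons - 2L
  aas <- sample(aaLetters, sum(bodyLens), replace = TRUE)
  codons <- character(length(aas))
  for (aa in aaLetters) {
    idx <- which(aas == aa)
    if (!length(idx)) next
    p <- profile[[aa]]
    codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  stopProb <- profile[["*"]]
  stops <- sample(names(stopProb), n, replace = TRUE, prob = stopProb)
  ends <- cumsum(bodyLens)
  starts <- ends - bodyLens + 1L
  seqs <- vapply(seq_len(n), function(i) {
    paste0("ATG",
           paste0(codons[seq.int(starts[i], length.out = bodyLens[i])],
                  collapse = ""),
           stops[i])
  }, character(1L))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Generate a per-transcript expression table
#'
#' TPM values are log-normal draws normalized to sum to one million; the
#' FPKM column is proportional to TPM, and `expected_count` scales TPM by
#' effective length as a real quantifier's output would.
#'
#' @param spec a [syntheticSpec()] object.
#' @param ids transcript ids.
#' @param lengths optional transcript lengths (nt) for the `length` /
#'   `effective_length` columns.
#' @return an expression `data.frame` in [readExpressionTable()] layout
#'   (plus `expected_count`).
#' @export
generateExpression <- function(spec, ids, lengths = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (!length(ids)) .txpValidationError("ids must be non-empty")
  set.seed(.childSeed(spec, 3L))
  raw <- rlnorm(length(ids), spec$tpmMeanLog, spec$tpmSdLog)
  tpm <- raw / sum(raw) * 1e6
  if (is.null(lengths)) lengths <- rep(NA_integer_, length(ids))
  efflen <- pmax(as.numeric(lengths) - 199, 1)
  data.frame(
    transcript_id = as.character(ids),
    tpm = tpm,
    fpkm = tpm * 0.85,
    length = as.integer(lengths),
    effective_length = efflen,
    expected_count = round(tpm * ifelse(is.na(efflen), 1, efflen) / 1e3, 2)
  )
}

#' Generate a 13-column alignment hit table
#'
#' One hit per query against a randomly chosen subject; the fraction of
#' the subject covered is drawn from `Beta(coverageShape1,
#' coverageShape2)` and realized as integer subject coordinates
#' (`s_start = 1 + floor(u * (L - span))`, `span = max(1, round(c * L))`),
#' keeping the realized coverage within 1/L of the draw.
#'
#' @param spec a [syntheticSpec()] object.
#' @param queryIds query (transcript/protein) ids.
#' @param subjectIds subject ids to sample from; defaults to one
#'   synthetic subject per query.
#' @param subjectLengths named integer vector of subject lengths
#'   (residues); defaults to uniform draws in 120..1200.
#' @param evalueRange range of `-log10(evalue)` to draw from; the default
#'   (5..180) straddles the usual 1e-20 cutoff.
#' @return a hit `data.frame` in [readTabularHits()] layout.
#' @export
generateHits <- function(spec, queryIds, subjectIds = NULL,
                         subjectLengths = NULL, evalueRange = c(5, 180)) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (!length(queryIds)) .txpValidationError("queryIds must be non-empty")
  set.seed(.childSeed(spec, 4L))
  n <- length(queryIds)
  if (is.null(subjectIds))
    subjectIds <- sprintf("sp%05d", seq_len(n))
  subj <- sample(subjectIds, n, replace = TRUE)
  if (is.null(subjectLengths))
    subjectLengths <- setNames(
      sample(120:1200, length(subjectIds), replace = TRUE),
      subjectIds)
  L <- as.integer(subjectLengths[subj])
  cov <- rbeta(n, spec$coverageShape1, spec$coverageShape2)
  span <- pmax(1L, as.integer(round(cov * L)))
  sstart <- 1L + as.integer(floor(runif(n) * (L - span)))
  send <- sstart + span - 1L
  ident <- round(runif(n, 25, 100), 1)
  ev <- 10^(-runif(n, evalueRange[1L], evalueRange[2L]))
  bits <- round(30 + span * ident / 100 * 2 + runif(n, 0, 20), 1)
  data.frame(
    query_id = as.character(queryIds), subject_id = subj,
    pct_identity = ident, aln_length = span,
    mismatches = as.integer(round(span * (100 - ident) / 100)),
    gap_opens = 0L,
    q_start = 1L, q_end = span,
    s_start = sstart, s_end = send,
    evalue = ev, bitscore = bits,
    subject_length = L
  )
}

#' Generate SignalP-style predictions
#'
#' Each protein is signal-positive with probability `spec$pSignal`;
#' positive records get a cleavage position of signal length plus one
#' (uniform over `spec$signalLengthRange`, capped below the protein
#' length when `proteinLengths` is given) and a D-score above the 0.45
#' cutoff, negatives below it.
#'
#' @param spec a [syntheticSpec()] object.
#' @param proteinIds protein ids.
#' @param proteinLengths optional named or positional protein lengths
#'   used to cap cleavage positions.
#' @return a `data.frame` in [readSignalp()] layout.
#' @export
generateSignalp <- function(spec, proteinIds, proteinLengths = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (!length(proteinIds)) .txpValidationError("proteinIds must be non-empty")
  set.seed(.childSeed(spec, 5L))
  n <- length(proteinIds)
  isSig <- runif(n) < spec$pSignal
  sigLen <- sample(seq(spec$signalLengthRange[1L],
                       spec$signalLengthRange[2L]), n, replace = TRUE)
  pos <- sigLen + 1L
  if (!is.null(proteinLengths))
    pos <- pmin(pos, as.integer(proteinLengths))
  d <- ifelse(isSig, runif(n, 0.46, 0.95), runif(n, 0.05, 0.44))
  data.frame(
    protein_id = as.character(proteinIds),
    d_score = round(d, 3),
    d_cutoff = 0.45,
    cleavage_pos = ifelse(isSig, pos, NA_integer_),
    is_signal = isSig
  )
}

.glycoCategories <- c(
  "sialyltransferase", "N-acetylgalactosaminyltransferase",
  "fucosyltransferase", "galactosyltransferase",
  "N-acetylglucosaminyltransferase", "mannosyltransferase",
  "glucosyltransferase", "xylosyltransferase",
  "glucuronyltransferase", "sulfotransferase")

#' Generate a glycogene reference annotation
#'
#' Categories are drawn from a ten-entry glycoenzyme vocabulary;
#' mechanisms favour inverting over retaining enzymes (0.5 / 0.3 / 0.2
#' unknown) and folds split 0.3 / 0.2 / 0.5 between GT-A, GT-B and
#' undetermined, mirroring the rough proportions reported for insect-cell
#' glycosyltransferase catalogues.
#'
#' @param spec a [syntheticSpec()] object.
#' @param nGenes number of reference genes (default 40).
#' @return a `data.frame` in [readGlycoReference()] layout.
#' @export
generateGlycoReference <- function(spec, nGenes = 40L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(.childSeed(spec, 6L))
  data.frame(
    gene_id = sprintf("GLY%03d", seq_len(nGenes)),
    category = sample(.glycoCategories, nGenes, replace = TRUE),
    mechanism = sample(.glycoMechanisms, nGenes, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    fold = sample(.glycoFolds, nGenes, replace = TRUE,
                  prob = c(0.3, 0.2, 0.5))
  )
}

#' Write a complete synthetic corpus to disk
#'
#' Generates and writes every input the pipeline consumes — CDS and
#' transcript FASTA, translated proteins, an RSEM-style expression table,
#' a 13-column hit table (transcripts vs. synthetic database subjects), a
#' glycogene reference with matching hits, a SignalP short-format table
#' and a protein-to-transcript id map — plus `truth.json` recording the
#' generator parameters and ground-truth codon profile.
#'
#' @param spec a [syntheticSpec()] object.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly;
#'   the generated objects are returned as the `"objects"` attribute.
#' @export
simulateCorpus <- function(spec, outdir) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  profile <- makeCodonProfile(spec)
  cds <- generateCds(profile, spec)
  ids <- names(cds)
  prot <- Biostrings::AAStringSet(sub("\\*$", "", as.character(
    Biostrings::translate(cds))))
  names(prot) <- paste0(ids, ".p1")
  idMap <- data.frame(protein_id = names(prot), transcript_id = ids)
  expr <- generateExpression(spec, ids,
                             lengths = Biostrings::width(cds))
  hits <- generateHits(spec, ids)
  glycoRef <- generateGlycoReference(spec)
  glycoSpec <- spec
  glycoSpec$seed <- .childSeed(spec, 8L)
  set.seed(.childSeed(spec, 7L))
  glycoHits <- generateHits(glycoSpec, sample(ids, min(100L, length(ids))),
                            subjectIds = glycoRef$gene_id,
                            evalueRange = c(10, 120))
  sp <- generateSignalp(spec, names(prot),
                        proteinLengths = Biostrings::width(prot))
  paths <- c(
    cds = file.path(outdir, "cds.fa"),
    transcripts = file.path(outdir, "transcripts.fa"),
    proteins = file.path(outdir, "proteins.fa"),
    expr = file.path(outdir, "expr.tsv"),
    hits = file.path(outdir, "hits.tsv"),
    glyco_ref = file.path(outdir, "glyco_ref.tsv"),
    glyco_hits = file.path(outdir, "glyco_hits.tsv"),
    signalp = file.path(outdir, "signalp.txt"),
    id_map = file.path(outdir, "id_map.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  writeFasta(cds, paths[["cds"]])
  writeFasta(cds, paths[["transcripts"]])
  writeFasta(prot, paths[["proteins"]])
  writeExpressionTable(expr, paths[["expr"]], dialect = "rsem")
  writeHitsTable(hits, paths[["hits"]])
  writeGlycoReference(glycoRef, paths[["glyco_ref"]])
  writeHitsTable(glycoHits, paths[["glyco_hits"]])
  writeSignalp(sp, paths[["signalp"]])
  .writeTsv(idMap, paths[["id_map"]], col.names = TRUE)
  truth <- list(spec = unclass(spec), codon_profile = profile,
                tpm_sum = sum(expr$tpm))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paths[["truth"]])
  objects <- list(profile = profile, cds = cds, proteins = prot,
                  expression = expr, hits = hits, glycoRef = glycoRef,
                  glycoHits = glycoHits, signalp = sp, idMap = idMap)
  attr(paths, "objects") <- objects
  invisible(paths)
}
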