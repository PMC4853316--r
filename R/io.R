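#' Read sequences from a FASTA file
#'
#' Reads nucleotide or protein FASTA into a `DNAStringSet` /
#' `AAStringSet`. Nucleotide sequences are uppercased and RNA `U` is
#' mapped to `T`, normalizing mixed-case assembler output. Record names
#' keep the full header line; the id (first whitespace-delimited token)
#' must be unique within the file.
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"` (default) or `"AA"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet];
#'   empty (with a warning) for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGT", "AC"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path))
    .txpValidationError(sprintf("input file not found: %s", path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(if (type == "DNA") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet())
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">"))
    .txpFormatError(sprintf(
      "not a FASTA file (first byte is not '>'): %s", path))
  x <- Biostrings::readBStringSet(path)
  ids <- .fastaIds(names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    .txpFormatError(sprintf("duplicate FASTA id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  if (any(Biostrings::width(x) == 0L))
    .txpFormatError("FASTA record with empty sequence")
  seqs <- toupper(as.character(x))
  out <- if (type == "DNA") {
    Biostrings::DNAStringSet(chartr("U", "T", seqs))
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- names(x)
  out
}

.fastaIds <- function(headers) sub("\\s.*$", "", headers)

#' Write sequences to a FASTA file
#'
#' @param x a `DNAStringSet` or `AAStringSet`.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a per-transcript expression table
#'
#' Supports two dialects: the RSEM `isoforms.results` layout (tab-separated
#' with a header containing at least `transcript_id`, `length`,
#' `effective_length`, `expected_count`, `TPM` and `FPKM`) and a generic
#' two-column `id<TAB>TPM` table with an optional header.
#'
#' @param path path to a tab-separated expression table.
#' @param dialect `"rsem"` (default) or `"generic"`.
#' @return a `data.frame` with columns `transcript_id`, `tpm`, `fpkm`,
#'   `length`, `effective_length` (`NA` where the dialect lacks them).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("t1\t12.5", "t2\t0"), f)
#' readExpressionTable(f, dialect = "generic")
#' @export
readExpressionTable <- function(path, dialect = c("rsem", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .txpValidationError(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (dialect == "rsem") {
    if (!length(lines))
      .txpFormatError(sprintf("empty expression table: %s", path))
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    needed <- c("transcript_id", "length", "effective_length",
                "expected_count", "TPM", "FPKM")
    missing <- setdiff(needed, header)
    if (length(missing))
      .txpFormatError(sprintf("expression table lacks column(s): %s",
                              paste(missing, collapse = ", ")))
    if (length(lines) == 1L) {
      warning("expression table has a header but no data rows: ", path)
      return(.emptyExpression())
    }
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n != length(header)))
      .txpFormatError(sprintf(
        "expression table row %d has %d fields, expected %d",
        which(n != length(header))[1L] + 1L,
        n[n != length(header)][1L], length(header)))
    m <- do.call(rbind, fields)
    colnames(m) <- header
    out <- data.frame(
      transcript_id = m[, "transcript_id"],
      tpm = .parseNum(m[, "TPM"], path, "TPM"),
      fpkm = .parseNum(m[, "FPKM"], path, "FPKM"),
      length = as.integer(.parseNum(m[, "length"], path, "length")),
      effective_length = .parseNum(m[, "effective_length"], path,
                                   "effective_length")
    )
  } else {
    if (!length(lines)) {
      warning("empty expression table: ", path)
      return(.emptyExpression())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L))
      .txpFormatError(sprintf(
        "generic expression table row %d does not have 2 fields",
        which(lengths(fields) != 2L)[1L]))
    # optional header: drop the first row when its TPM field is not numeric
    if (is.na(suppressWarnings(as.numeric(fields[[1L]][2L]))))
      fields <- fields[-1L]
    if (!length(fields)) {
      warning("expression table has a header but no data rows: ", path)
      return(.emptyExpression())
    }
    m <- do.call(rbind, fields)
    out <- data.frame(
      transcript_id = m[, 1L],
      tpm = .parseNum(m[, 2L], path, "TPM"),
      fpkm = NA_real_,
      length = NA_integer_,
      effective_length = NA_real_
    )
  }
  dup <- out$transcript_id[duplicated(out$transcript_id)]
  if (length(dup))
    .txpFormatError(sprintf("duplicate transcript_id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  bad <- which(out$tpm < 0)
  if (length(bad))
    .txpFormatError(sprintf("negative TPM in data row %d", bad[1L]))
  rownames(out) <- NULL
  out
}

.emptyExpression <- function() {
  data.frame(transcript_id = character(), tpm = numeric(),
             fpkm = numeric(), length = integer(),
             effective_length = numeric())
}

.parseNum <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !(x %in% c("NA", ""))
  if (any(bad))
    .txpFormatError(sprintf("unparseable %s value '%s' in %s",
                            what, x[which(bad)[1L]], path))
  v
}

#' Write an expression table
#'
#' @param x data.frame as returned by [readExpressionTable()].
#' @param path output path.
#' @param dialect `"rsem"` or `"generic"`.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path, dialect = c("rsem", "generic")) {
  dialect <- match.arg(dialect)
  if (dialect == "rsem") {
    out <- data.frame(
      transcript_id = x$transcript_id,
      gene_id = x$transcript_id,
      length = x$length,
      effective_length = x$effective_length,
      expected_count = if (!is.null(x$expected_count)) x$expected_count
                       else NA_real_,
      TPM = x$tpm,
      FPKM = x$fpkm
    )
    .writeTsv(out, path, col.names = TRUE)
  } else {
    .writeTsv(data.frame(x$transcript_id, x$tpm), path, col.names = FALSE)
  }
  invisible(path)
}

.writeTsv <- function(x, path, col.names = TRUE, comment = NULL) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names, eol = "\n", na = "NA")
}

.hitColumns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore", "subject_length")

#' Read tabular alignment hits
#'
#' Reads a tab-separated hit table in the standard 12-column tabular
#' alignment layout with the subject length appended as a 13th column.
#' Subject length is required because full-length assessment computes the
#' fraction of the homolog's residues covered by each hit; the standard
#' 12-column format does not carry it. Alternatively a 12-column file may
#' be combined with a separate id-to-length lookup via `subjectLengths`.
#' Lines starting with `#` are ignored.
#'
#' @param path path to the hit table.
#' @param subjectLengths optional named numeric vector (or two-column
#'   data.frame, id then length) supplying subject lengths for 12-column
#'   input.
#' @return a `data.frame` with columns
#'   `query_id, subject_id, pct_identity, aln_length, mismatches,
#'   gap_opens, q_start, q_end, s_start, s_end, evalue, bitscore,
#'   subject_length`, in file order. Coordinates are 1-based inclusive.
#' @export
readTabularHits <- function(path, subjectLengths = NULL) {
  if (!file.exists(path))
    .txpValidationError(sprintf("input file not found: %s", path))
  if (!is.null(subjectLengths) && is.data.frame(subjectLengths))
    subjectLengths <- setNames(as.numeric(subjectLengths[[2L]]),
                               as.character(subjectLengths[[1L]]))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  data <- lines[keep]
  lineno <- which(keep)
  if (!length(data)) return(.emptyHits())
  fields <- strsplit(data, "\t", fixed = TRUE)
  n <- lengths(fields)
  expected <- if (is.null(subjectLengths)) 13L else 12L
  if (any(n != expected)) {
    i <- which(n != expected)[1L]
    if (is.null(subjectLengths) && n[i] == 12L)
      .txpFormatError(sprintf(paste0(
        "line %d has 12 columns; hit tables need the subject length as a ",
        "13th column (regenerate with it appended, e.g. blast outfmt ",
        "'6 std slen') or pass subjectLengths"), lineno[i]))
    .txpFormatError(sprintf("line %d has %d columns, expected %d",
                            lineno[i], n[i], expected))
  }
  m <- do.call(rbind, fields)
  num <- function(j, what, int = FALSE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      .txpFormatError(sprintf("unparseable %s '%s' on line %d",
                              what, m[which(is.na(v))[1L], j],
                              lineno[which(is.na(v))[1L]]))
    if (int) as.integer(v) else v
  }
  out <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "identity"),
    aln_length = num(4L, "alignment length", int = TRUE),
    mismatches = num(5L, "mismatch count", int = TRUE),
    gap_opens = num(6L, "gap open count", int = TRUE),
    q_start = num(7L, "q_start", int = TRUE),
    q_end = num(8L, "q_end", int = TRUE),
    s_start = num(9L, "s_start", int = TRUE),
    s_end = num(10L, "s_end", int = TRUE),
    evalue = num(11L, "e-value"),
    bitscore = num(12L, "bitscore")
  )
  if (is.null(subjectLengths)) {
    out$subject_length <- num(13L, "subject length", int = TRUE)
  } else {
    sl <- subjectLengths[out$subject_id]
    if (anyNA(sl))
      .txpFormatError(sprintf(
        "no subject length supplied for subject '%s'",
        out$subject_id[which(is.na(sl))[1L]]))
    out$subject_length <- as.integer(sl)
  }
  bad <- which(out$s_start < 1L | out$s_end < 1L |
               out$s_start > out$subject_length |
               out$s_end > out$subject_length)
  if (length(bad))
    .txpFormatError(sprintf(
      "subject coordinates outside [1, subject_length] on line %d",
      lineno[bad[1L]]))
  if (any(out$evalue < 0))
    .txpFormatError("negative e-value in hit table")
  rownames(out) <- NULL
  out
}

.emptyHits <- function() {
  out <- data.frame(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric(), subject_length = integer()
  )
  out
}

#' Write tabular alignment hits (13-column layout)
#'
#' @param x hits `data.frame` as returned by [readTabularHits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsTable <- function(x, path) {
  out <- x[, .hitColumns]
  out$evalue <- formatC(out$evalue, format = "g", digits = 6)
  .writeTsv(out, path, col.names = FALSE)
  invisible(path)
}

#' Read SignalP v4 short-format predictions
#'
#' Parses the short (one line per protein) output of SignalP 4.x. Each
#' data line carries 12 whitespace-separated fields
#' (`name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks`); the
#' D-score is compared to its cutoff for the Y/N secretion call, and the
#' Ymax position is the predicted first residue of the mature protein.
#' Output of other SignalP major versions is rejected.
#'
#' @param path path to a SignalP short-format file.
#' @return a `data.frame` with columns `protein_id`, `d_score`,
#'   `d_cutoff`, `cleavage_pos` (first mature residue; `NA` for
#'   non-signal proteins) and `is_signal`.
#' @export
readSignalp <- function(path) {
  if (!file.exists(path))
    .txpValidationError(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  ver <- grep("SignalP-", comments, value = TRUE)
  if (length(ver) && !any(grepl("SignalP-4", ver)))
    .txpFormatError(paste0(
      "unsupported SignalP version in header ('",
      sub(".*?(SignalP-[0-9.]+).*", "\\1", ver[[1L]]),
      "'); only SignalP 4 short format is supported"))
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  data <- lines[keep]
  lineno <- which(keep)
  if (!length(data))
    return(data.frame(protein_id = character(), d_score = numeric(),
                      d_cutoff = numeric(), cleavage_pos = integer(),
                      is_signal = logical()))
  fields <- strsplit(trimws(data), "[[:space:]]+")
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    .txpFormatError(sprintf(
      "malformed SignalP data line %d (%d fields, expected 12)",
      lineno[bad[1L]], lengths(fields)[bad[1L]]))
  m <- do.call(rbind, fields)
  numcol <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      .txpFormatError(sprintf("unparseable %s on line %d",
                              what, lineno[which(is.na(v))[1L]]))
    v
  }
  call <- m[, 10L]
  if (!all(call %in% c("Y", "N")))
    .txpFormatError(sprintf("unexpected signal call '%s' on line %d",
                            call[!call %in% c("Y", "N")][1L],
                            lineno[which(!call %in% c("Y", "N"))[1L]]))
  out <- data.frame(
    protein_id = m[, 1L],
    d_score = numcol(9L, "D-score"),
    d_cutoff = numcol(11L, "D-cutoff"),
    cleavage_pos = as.integer(numcol(5L, "cleavage position")),
    is_signal = call == "Y"
  )
  out$cleavage_pos[!out$is_signal] <- NA_integer_
  if (any(out$is_signal & out$cleavage_pos < 2L, na.rm = TRUE))
    .txpFormatError("signal-positive record with cleavage position < 2")
  rownames(out) <- NULL
  out
}

#' Write SignalP v4 short-format predictions
#'
#' @param x `data.frame` as returned by [readSignalp()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignalp <- function(x, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# SignalP-4.1 euk predictions",
               paste("# name Cmax pos Ymax pos Smax pos",
                     "Smean D ? Dmaxcut Networks-used")), con)
  pos <- ifelse(is.na(x$cleavage_pos), 1L, x$cleavage_pos)
  lines <- sprintf(
    "%s  %.3f  %d  %.3f  %d  %.3f  %d  %.3f  %.3f %s %.3f  SignalP-noTM",
    x$protein_id, x$d_score, pos, x$d_score, pos, x$d_score,
    pmax(1L, pos - 1L), x$d_score, x$d_score,
    ifelse(x$is_signal, "Y", "N"), x$d_cutoff)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.glycoMechanisms <- c("inverting", "retaining", "unknown")
.glycoFolds <- c("GT-A", "GT-B", "unknown")

#' Read a glycogene reference annotation table
#'
#' The reference lists each glycan-synthesis gene with its functional
#' category (free vocabulary, e.g. sialyltransferase, fucosyltransferase),
#' catalytic mechanism (`inverting`, `retaining` or `unknown`) and
#' structural fold (`GT-A`, `GT-B` or `unknown`).
#'
#' @param path path to a TSV with header
#'   `gene_id, category, mechanism, fold`.
#' @return a validated `data.frame` with those four columns.
#' @export
readGlycoReference <- function(path) {
  if (!file.exists(path))
    .txpValidationError(sprintf("input file not found: %s", path))
  x <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = "character", comment.char = "#")
  needed <- c("gene_id", "category", "mechanism", "fold")
  missing <- setdiff(needed, colnames(x))
  if (length(missing))
    .txpFormatError(sprintf("glycogene reference lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  x <- x[, needed]
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup))
    .txpFormatError(sprintf("duplicate gene_id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(trimws(x$category))))
    .txpFormatError("empty category in glycogene reference")
  badm <- setdiff(unique(x$mechanism), .glycoMechanisms)
  if (length(badm))
    .txpFormatError(sprintf(
      "unknown mechanism '%s'; allowed values: %s", badm[1L],
      paste(.glycoMechanisms, collapse = ", ")))
  badf <- setdiff(unique(x$fold), .glycoFolds)
  if (length(badf))
    .txpFormatError(sprintf(
      "unknown fold '%s'; allowed values: %s", badf[1L],
      paste(.glycoFolds, collapse = ", ")))
  rownames(x) <- NULL
  x
}

#' Write a glycogene reference annotation table
#'
#' @param x `data.frame` as returned by [readGlycoReference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGlycoReference <- function(x, path) {
  .writeTsv(x[, c("gene_id", "category", "mechanism", "fold")], path,
            col.names = TRUE)
  invisible(path)
}
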