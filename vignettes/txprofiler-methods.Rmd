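---
title: "Methods behind txprofiler"
author: "txprofiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind txprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txprofiler)
```

# Scope and assumptions

txprofiler covers the quantitative, post-assembly side of characterizing
a transcriptome assembled for a protein expression host: assembly
statistics weighted by expression, full-length assessment from homology
hits, codon-usage bias, glycogene cataloguing and signal-peptide
ranking. It deliberately does **not** run the upstream tools (assembler,
aligner, quantifier, predictor); it consumes their standard tabular and
FASTA outputs, and its synthetic generator produces files in exactly
those dialects so every stage is testable offline.

Throughout, sequences are handled as Biostrings objects, tabular records
as plain data frames, and the codon-usage core as S4 classes
(`CodonCountTable`, `RSCUTable`) whose validity methods enforce the
defining invariants on construction.

# Assembly statistics

**N50.** Lengths are sorted in decreasing order and the N50 is the
length at which the running base sum first reaches half the total. The
result is always one of the observed lengths. Note that N50 is *not*
necessarily at least the median; no such relation is assumed anywhere.

**ExN50.** The curve's "x% of the data" is interpreted as x% of total
TPM mass, the standard construction for expression-weighted N50 curves:
the Ex subset is the shortest prefix of the TPM-descending ordering
whose cumulative TPM reaches `x/100 * sum(TPM)`, and ExN50 is the N50 of
that subset's lengths. Because the legend-style phrasing of this
statistic is often ambiguous, the package also reports `subset_size` and
`min_tpm` for every point so a reader can verify which subset was used.
Sorting ties are broken deterministically (TPM descending, then length
descending, then id ascending) so the curve is bit-reproducible; the
subset index is clamped to the full set at x = 100 to absorb one-ulp
differences between the running sum and the total. Transcripts lacking
an expression record are treated as TPM 0 with a warning rather than an
error, since quantifiers commonly drop zero-count transcripts; a total
TPM of zero is an error because the curve is undefined.

**TPM filtering** is inclusive: eliminating transcripts "below" a
threshold keeps exactly those with TPM ≥ threshold.

**GC content** is pooled over all sequences and computed over
unambiguous bases only (N and IUPAC ambiguity codes are excluded from
numerator and denominator), i.e. the GC of the known bases. The median
of an even-sized length set is the mean of the two central values.

# Full-length assessment

Transcripts are assessed by their single best database hit: hits above
the e-value cutoff (default `1e-20`, comparison inclusive) are
discarded, and per query the maximum-bitscore hit wins, with ties broken
by smaller e-value and then input order.

Coverage of the subject (the known homolog) is the subject-coordinate
span `(|s_end - s_start| + 1) / subject_length`, clamped to 1. The
alignment-length column is *not* used because it counts gap columns and
can exceed the subject span; "fraction of the homolog's residues
covered" is the quantity of interest. Coordinates are 1-based inclusive
and orientation-free (start/end may be swapped). Multiple HSPs of a
query–subject pair are not merged; the single best HSP defines coverage.
Merging or chaining HSPs would require tiling logic whose behaviour on
overlapping segments is not standardized, and is out of scope.

Because subject length is not part of the standard 12-column tabular
alignment format, the hit reader requires it as a 13th column (as
produced by, e.g., adding `slen` to the output format) or, as a fallback,
a separate id-to-length lookup. A 12-column file without the lookup is
rejected with instructions rather than silently given coverage of NA.

Binning uses half-open `(lower, upper]` percentage bins with the top bin
closed and exact zeros placed in the lowest bin, and the cumulative
series is the suffix sum from the 100 % bin downward — "how many
transcripts cover more than `lower` percent of their homolog".

# Codon usage

**Counting.** Sequences are presumed in-frame CDS from position 1 and
walked 5′→3′ in non-overlapping triplets; a trailing partial triplet is
dropped and any triplet containing a non-ACGT character is skipped (and
counted), not fatal — assembled CDS routinely contain Ns. The default
length filter keeps sequences of ≥ 300 nt (100 amino acids), the
conventional cutoff separating credible ORFs from noise; the boundary is
inclusive because "longer than 100 amino acids (300 bp)" equates the two
and the inclusive reading is the least surprising. The filter is a
parameter everywhere it appears.

**RSCU.** For amino acid *i* with *nᵢ* synonymous codons and counts
*xᵢⱼ*, `RSCU_ij = x_ij / ((1/n_i) Σ_j x_ij)`. Families with zero total
yield `NA` (the formula is 0/0 there) — not 0 and not 1, and such
families are excluded from downstream range/SD statistics. The family
sum invariant (Σ RSCU = *nᵢ* whenever observed) is enforced by the
`RSCUTable` validity method on every construction. Stop codons are
excluded by default, since cross-species comparisons are usually drawn
over the 20 amino acids; `includeStop = TRUE` treats the three stops as
one family.

**Bias statistics.** Range (max − min), the codons attaining the
extremes (alphabetically first codon on ties) and the **population**
standard deviation (divisor *nᵢ*): the family is the entire population
of interest, not a sample from a larger codon set. Single-codon amino
acids have range and SD exactly 0.

The genetic code is fixed to the standard nuclear code (NCBI table 1),
which all commonly compared expression hosts use for nuclear CDS.

# Glycogene profiling

A reference gene is present when at least one hit passes all of:
e-value ≤ `1e-20`, identity ≥ 30 %, subject coverage ≥ 0.5. Published
glycogene catalogues are typically finalized by manual curation against
secondary databases; these explicit thresholds are a reproducible
substitute, and counts obtained with them will not exactly match
manually curated catalogues. The defaults are deliberately conservative
homology-calling values; all three are parameters. Presence calling is
monotone in the thresholds (loosening any of them can only add genes), a
property the test suite checks.

A gene's expression is the TPM of its single best supporting transcript,
not a sum over all matching transcripts — one expression mark per gene.
Mechanism proportions are taken over `{inverting, retaining, unknown}`
and fold proportions over `{GT-A, GT-B, unknown}`, each axis summing
to 1 over present genes; with no present genes the result is explicitly
empty rather than NaN.

# Signal-peptide ranking

Only signal-positive predictions are ranked. The predictor reports the
first residue of the mature protein, so the signal sequence is residues
1 to `cleavage_pos − 1`; every emitted signal sequence is checked to be
a prefix of its protein. Ranking is by TPM descending with D-score and
then id as tie-breaks. Proteins not starting with methionine are flagged
as possibly 5′-truncated (the assembly may miss the true start) but are
never removed — the flag marks candidates for manual review. A
prediction whose transcript has no expression record is kept at TPM 0
with a warning, consistent with the ExN50 missing-expression rule;
identical signal sequences are not de-duplicated. When one transcript
yields several predicted proteins, each is ranked independently.

Only the SignalP v4 short format is parsed; other major versions changed
the column layout and are rejected with a clear message rather than
mis-parsed.

# The synthetic generator

The generator emulates the *shape* of the real inputs, with known ground
truth:

* CDS: ATG start, i.i.d. uniform amino-acid body, codons drawn from
  per-amino-acid Dirichlet(α) probability vectors, single stop, length
  log-normal(log 900, 0.6) floored at 90 nt — matching the scale of
  typical de novo assemblies whose mean contig length is near 1–1.3 kb.
  The Dirichlet concentration α = 1 gives visible but not degenerate
  bias; the generated RSCU converges to `n_i · p_j`, which is the basis
  of the parameter-recovery test.
* Expression: log-normal(0, 2) draws normalized to 1e6 — a heavy-tailed
  TPM distribution in which a few transcripts dominate, as in real
  cell-line libraries.
* Hits: one hit per query; subject coverage Beta(2, 1.5) (mean 4/7, most
  hits covering over half their homolog) realized as integer coordinates
  `s_start = 1 + floor(u(L − span))`, `span = max(1, round(cL))`, which
  keeps the realized coverage within 1/L of the draw.
* SignalP: Bernoulli(0.15) positives — a plausible secretome fraction —
  with cleavage positions drawn from signal lengths of 15–30 residues
  plus one, and D-scores consistent with the 0.45 cutoff.

A single master seed is fanned out through a fixed linear-congruential
step to per-generator child seeds, so each generator is individually
reproducible and the full corpus is byte-identical across runs.

What the generator does **not** emulate: read-level errors, chimeric or
fragmented contigs, isoform redundancy, biased amino-acid composition,
correlated expression between homologous transcripts, or the codon usage
of any named species. Passing tests therefore demonstrate the
correctness of the computations and the robustness of the parsers, not
biological verisimilitude of any particular host.

# Numerical choices and degenerate inputs

* RSCU family sums are checked to `1e-9`; comparisons of RSCU against
  independent implementations agree to machine precision.
* All sorts that affect output use explicit multi-key orderings with the
  radix method, so ordering is locale-independent and reproducible.
* Empty inputs are either warnings with empty results (empty FASTA,
  header-only expression tables, empty hit lists) or errors when the
  statistic is undefined (N50 of nothing, ExN50 with zero total TPM,
  codon counts with no surviving sequence).
* Duplicate ids are errors in every reader — summing or keeping-first
  would silently corrupt downstream joins.
* Parsers never drop data rows silently: data rows plus comment/blank
  lines account for every line of a tabular file.

# Problem sizes

The test suite runs property checks at 500–1,000 random instances per
operation and the parameter-recovery check on a ~900k-codon corpus
(2,500 CDS); the full suite completes in about three minutes on one
core, and `scripts/acceptance.R` in about one. These sizes were chosen
to give the statistical checks comfortable margins (the recovery error
at that corpus size is ~0.02–0.03 against a 0.05 bound) while staying
desk-scale.

# Known limitations

* Coverage assessment uses one HSP per query; fragmented alignments of a
  truly full-length transcript under-estimate coverage.
* Glycogene presence from thresholded homology cannot distinguish close
  paralogs; curation against secondary databases remains advisable
  before engineering decisions.
* The generic expression dialect carries TPM only; FPKM-based analyses
  need the full quantifier table.
* The expression-ranked signal-peptide list inherits the predictor's
  false calls; the truncation flag catches missing starts but not
  internal mispredictions.
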