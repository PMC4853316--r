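Package: txprofiler
Title: Assembly Statistics, Codon Usage and Secretion-Oriented Profiling
    for De Novo Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative post-assembly analysis of de novo transcriptomes
    built for recombinant protein expression hosts. Computes assembly
    summaries (N50, GC content, length statistics), expression-weighted
    ExN50 curves and TPM-threshold transcript counts; assesses transcript
    full-lengthness by best-hit subject coverage against a protein database
    with binned cumulative histograms; counts codons over coding sequences,
    computes relative synonymous codon usage (RSCU) and per-amino-acid bias
    statistics for cross-species comparison; profiles glycogene presence,
    categories and catalytic mechanism/fold proportions from homology hits;
    and ranks predicted signal peptides by transcript expression. A seeded
    synthetic-data generator produces every input format the pipeline
    consumes, with known ground truth, so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr
biocViews: Transcriptomics, Sequencing, Coverage, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
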