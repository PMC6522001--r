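Package: tfcoop
Title: Tissue-Specific Transcription Factor Cooperation from Promoter
    Motif Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tissue-specific transcription factor (TF)
    cooperations from RNA-seq expression tables and promoter sequences.
    Selects tissue-specific genes by the two-thirds expression rule,
    builds tissue-filtered non-redundant position weight matrix (PWM)
    libraries, predicts binding sites by log-odds scanning with
    error-rate-calibrated cutoffs, scores TF-pair co-occurrence under
    5-20 bp distance constraints with pointwise mutual information (PMI),
    separates specific from generally important pairs by subtracting the
    background cooperation level estimated on dinucleotide-shuffled
    sequence sets, and emits per-tissue cooperation networks. Includes a
    synthetic-data generator with planted tissue-specific genes and
    distance-coupled motif pairs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
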