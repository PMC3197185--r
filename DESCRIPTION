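Package: TransProteo
Title: Transcriptome-Derived Protein Search Databases and Spectral-Count
    Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for using a de novo assembled transcriptome as the search
    model for shotgun proteomics of organisms without a sequenced genome.
    Builds annotated six-frame protein search databases from assembled
    transcripts (best-BLAST-hit header transfer, header deduplication,
    reversed-decoy and contaminant concatenation), performs in silico tryptic
    digestion and peptide-to-protein mapping, filters peptide-spectrum
    matches to a target-decoy false discovery rate under two-peptide and
    probability thresholds, quantifies differential protein abundance by
    normalized spectral abundance factors (NSAF) with one-way ANOVA, and maps
    quantified proteins onto a configurable fatty-acid/triacylglycerol
    pathway report. A seeded simulator generates synthetic transcriptomes,
    annotation tables and replicate PSM tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Transcriptomics, Software
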