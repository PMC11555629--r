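Package: IOscore
Title: Cross-Species Paired Expression-Ratio Scoring for Gonadal
    Transcriptome Meta-Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a batch-robust meta-analysis of paired
    intersexual-gonad versus ovary RNA-seq expression across sequentially
    hermaphroditic fish species. Expression changes are measured per curated
    sample pair as a pseudocount-adjusted log2 TPM ratio (the IO-ratio),
    classified against a fold-change cutoff, and summarised per transcript
    and species as an integer IO-score (upregulated pairs minus
    downregulated pairs). One-to-one orthologs are inferred as reciprocal
    best hits of tabular homology searches against a hub species, ortholog
    groups common to all species are consolidated on hub protein IDs, and
    per-species IO-scores are summed into total IO-scores from which
    differentially expressed genes are called at a threshold derived as a
    fraction of the attainable maximum. A synthetic-data generator with
    planted effects provides fully reproducible fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Sequencing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'expression.R'
    'scoring.R'
    'orthology.R'
    'aggregate.R'
    'simulate.R'
    'pipeline.R'
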