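Package: ligandTargets
Title: Multi-Omic Candidate Selection for HLA Peptide-Based Immunotherapy Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements an integrative candidate-selection workflow for
    nominating immunotherapy target genes in tumors with a low mutational
    load. Tumor-exclusive HLA-presented peptides from immunopeptidome
    detection data are mapped to their source genes and intersected with
    genes from pathways enriched across a tumor cohort, scored by
    single-sample gene set enrichment (rank-weighted ECDF scoring) with
    cell-of-origin signature subtraction. Candidates are then validated in a
    second cohort by signature re-enrichment, a kernel-density minimal
    expression threshold, paired and unpaired tumor-versus-normal induction
    tests, and an expression-stability (coefficient of variation) filter,
    and finally characterized by correlation rules against DNA methylation,
    somatic mutations, tissue metabolites, and immune-oncology protein
    markers. A seeded synthetic multi-omics cohort generator with planted
    ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, Transcriptomics, Proteomics, ImmunoOncology,
    Software
RoxygenNote: 7.3.3
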