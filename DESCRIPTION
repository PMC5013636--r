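Package: sccprogress
Title: Cross-Species Genomic Analysis of Squamous Cell Carcinoma Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the genomic progression of cutaneous squamous
    cell carcinoma from chronically sun-exposed skin through actinic
    keratosis (and the papilloma stage of ultraviolet-driven mouse models) to
    invasive carcinoma. Implements 96-class trinucleotide mutation catalogues
    with spectrum, load, recurrently-mutated-gene and within-patient
    site-overlap statistics; non-smooth non-negative matrix factorization for
    sparse mutational-signature deconvolution and exposure refitting;
    per-gene linear mixed-effects progression modelling with
    early/late/stepwise designation and one-to-one homolog intersection
    across species; ranked-list gene-set enrichment with permutation
    significance, transcription-factor target concordance filtering and
    co-target networks; small-RNA read filtering, parts-per-million miRNA
    quantification and miRNA-mRNA anti-correlated functional-pair discovery;
    and z-score-sum expression signatures with quartile log-rank survival
    testing. A seeded synthetic-data generator produces every input type with
    known ground truth so the whole pipeline is testable without access to
    protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    Biostrings,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
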