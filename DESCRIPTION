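Package: seqexpr
Title: Modelling Gene Expression from Nucleotide-Level Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Explains per-sample gene expression from nucleotide-level
    sequence features of eight gene-associated regions (distal upstream,
    core and distal downstream promoter segments, 5'UTR, CDS, 3'UTR,
    constitutive introns and the downstream flanking region). Provides
    region segmentation and sequence extraction from genome plus
    annotation, (di/tri)nucleotide composition, PWM log-odds motif scores
    and pentamer-table DNA-shape features, per-sample lasso regression
    with cross-validated evaluation and negative controls, forward
    selection over region feature blocks, stability selection, regression
    tree stratification of genes by model error, and topologically
    associated domain (TAD) compositional-signature and enrichment
    statistics. Includes a synthetic-data generator with planted ground
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    glmnet,
    rpart,
    jsonlite,
    MASS,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
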