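Package: stemtraj
Title: Single-Cell Analysis of Stem-Cell Aging Along the Intestinal
    Maturation Trajectory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying how aging and geroprotector
    treatment reshape intestinal stem cells and the maturation of their
    progeny in single-cell RNA-seq data. Implements expression-ratio
    compartment analysis of stem signature repression, control-bin pathway
    module scoring, negative-binomial mixed-model differential expression
    with library-size offsets, preranked gene-set enrichment analysis with a
    permutation null, and a principal-graph maturation trajectory with
    main/side dichotomization, branch-point transition testing, emergence
    delays and a co-expression delay index. Ships a ground-truthed synthetic
    cohort generator emulating a young / old / old+metformin / old+rapamycin
    design for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    MASS,
    lme4,
    igraph,
    jsonlite,
    fgsea
Suggests:
    irlba,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
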