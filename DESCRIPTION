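Package: methylcomp
Title: Cell-Type Composition Estimation and Confounding Diagnostics for
    DNA Methylation Arrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-based estimation of cell-type proportions from
    Illumina-style DNA methylation beta values (signature CpG selection from
    flow-sorted reference data followed by constrained least-squares
    projection), together with diagnostics for composition-driven
    confounding in epigenome-wide association studies: per-probe composition
    ANOVA, variance partitioning, principal-component/composition
    correlation, age-trend summaries, naive covariate and two-step
    remove-unwanted-variation (RUV) adjustment, the two-cell-type CETS
    transform with its closed-form bias decomposition, composition-filtered
    gene-set over-representation, and a seed-deterministic synthetic-data
    generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: DNAMethylation, Epigenetics, MethylationArray, BatchEffect,
    CellBiology, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
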