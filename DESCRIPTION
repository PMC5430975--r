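Package: coexPK
Title: Co-Expression Networks, Differential Connectivity and
    Pharmacokinetic Trait Integration for Liver RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline relating bulk liver RNA-seq profiles of
    drug-treated and untreated animals to pharmacokinetic (PK) phenotypes.
    Counts are filtered on CPM, normalized by the trimmed mean of M-values,
    expressed as (log2) RPKM and adjusted for batch; treatment contrasts are
    tested with negative-binomial likelihood-ratio tests; an unsigned
    weighted co-expression network is built with a soft threshold chosen by
    the scale-free topology criterion, modules are detected by a static
    height cut of the average-linkage TOM dendrogram and merged on eigengene
    correlation; module eigengenes are correlated with PK traits and modules
    are selected by the joint correlation, significance and
    differential-expression filter; per-condition scaled connectivity yields
    differential connectivity hub genes and Kolmogorov-Smirnov comparisons;
    module gene sets are tested for term enrichment against the expressed
    background. A synthetic-data generator with planted modules, treatment
    effects, batch effects and module-correlated PK traits makes every stage
    testable without access to the original animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
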