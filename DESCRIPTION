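Package: rnakit
Title: Modular Toolbox for RNA-Seq Count-Matrix Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolbox for tabular RNA-seq analysis: validated count
    matrices and differential-expression tables with per-table history;
    filtering and set operations (including majority-vote intersections);
    between-sample normalization (median-of-ratios, TMM, CPM, quantile,
    Box-Cox power transform); exploratory summaries (PCA, sample correlation,
    volcano classification); clustering with biology-specific time-course
    distances (YS1, YR1, jackknife correlation), gap-statistic model
    selection, density-based clustering and a clique-based ensemble
    clusterer; a multi-method enrichment engine (hypergeometric, ELIM
    ontology decorrelation, permutation, minimum-hypergeometric ranked-list
    and continuous-attribute tests with FDR control); serializable analysis
    pipelines with undo; and synthetic-data generators for all supported
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    limma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
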