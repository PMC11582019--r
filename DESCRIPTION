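Package: resptyper
Title: Response Typing of Soil Microbial Population Dynamics Under
    Factorial Top-Down and Bottom-Up Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved 16S rRNA gene amplicon
    data from soil microcosm experiments crossing top-down control
    (bacterivorous nematode grazing) with bottom-up control (maize litter
    amendment). Transforms ASV read counts to absolute abundances using
    qPCR totals, selects dominant and responsive ASVs via Hill-number
    dominance, replicate prevalence and Pareto abundance-range filters,
    classifies per-treatment abundance trajectories into five canonical
    response types by k-means clustering with template-guided merging,
    assembles cross-treatment response patterns and succession groups,
    performs compositional beta-diversity analysis (Bayesian-multiplicative
    zero replacement, centred log-ratio transform, Aitchison PCA, variance
    partitioning), and computes soil respiration rates from alkali-trap
    titration records. Includes a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    mclust,
    jsonlite,
    knitr
biocViews: Microbiome, Metagenomics, TimeCourse, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
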