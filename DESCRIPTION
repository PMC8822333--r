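Package: voxMetab
Title: Integration of Voxel-Wise Brain Gray Matter with Untargeted CSF
    Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for integrating voxel-based morphometry of
    structural brain MRI with untargeted LC-MS metabolomics of
    cerebrospinal fluid in case/control cohorts (mild cognitive
    impairment versus cognitively normal). Implements LC-MS feature-table
    preprocessing (replicate QC, median summarization, empirical-Bayes
    batch correction, group-wise missingness filtering with half-minimum
    imputation, log2 transform, quantile normalization), gray-matter mask
    construction and cross-validated PLS-DA voxel selection by VIP and
    percent mean difference, bipartite voxel-metabolite correlation
    networks with an automatic cutoff rule and modularity community
    detection, atlas-based brain-region annotation with 3D contiguity
    testing, m/z adduct-based pathway enrichment with Fisher exact and
    permutation p-values, and a stratified train/validation replication
    analysis. A synthetic-data generator with planted atrophy regions,
    coupled metabolite features and a planted enriched pathway supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma,
    sva,
    mixOmics,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metabolomics, MassSpectrometry, Network, BatchEffect,
    Preprocessing, Pathways
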