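Package: hdomics
Title: Peripheral-Tissue Multi-Omics Toolkit for Huntington Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and inference tools for desk-scale multi-omics
    studies of Huntington disease peripheral tissues: TMT 10plex
    peptide-spectrum-match (PSM) processing (signal filtering, isotopic
    impurity correction, sum-scaling normalization, reference log-ratios,
    peptide collapse, protein aggregation), sample quality control
    (median/IQR control charts, a dual-criterion PCA-ellipse plus
    standardized-connectivity outlier detector, count prevalence filtering,
    covariate factorization), iterative-PCA imputation with quantile
    normalization and linear-model covariate removal, a
    reproducibility-optimized bootstrap test statistic with permutation
    false discovery rates for two-group differential abundance, HTT
    haplotype construction, frequency-based naming and clustering from
    phased genotypes at 21 defining variants, and seeded synthetic-data
    generators emulating the statistical structure of each input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    ape
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
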