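Package: WZdynamics
Title: Population Genetics and Dynamics of WZ/ZZ Sex Determination with
    Intersex Males
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying female-heterogametic (WZ/ZZ) sex
    determination systems in which part of the WZ progeny emerge as
    intersex functional males, as in the Australian redclaw crayfish.
    Provides exact Mendelian cross tables for the three sex genotypes
    (ZZ, WZ, WW) including the WZ-male x WZ-female cross that yields
    viable WW females, a discrete-time density-independent four-class
    projection model with its long-term stable distribution and growth
    analyses, chi-square goodness-of-fit tests for progeny segregation
    ratios, cohort phenotype/genotype tallies, a presence/absence
    screen for W-linked RAD-tag sex markers, and seeded generators for
    synthetic crosses, pond experiments, native cohorts and tag
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, PopulationGenetics, Software
RoxygenNote: 7.3.3
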