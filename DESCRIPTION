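Package: seedQuant
Title: Quantification of Alpha-Synuclein Seeding Assays, Biosensor
    Imaging and Cohort Association Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores real-time quaking-induced conversion (RT-QuIC)
    thioflavin-T kinetic curves (plate-level fluorescence threshold,
    time to threshold, protein aggregation rate, plateau fluorescence,
    replicate aggregation and batch coefficient-of-variation QC),
    quantifies two-channel fluorescence micrographs (FRET inclusion
    detection by eccentricity/area filtering and neurite length per
    nucleus by skeletonization), ordinalizes assay outcomes and fits
    covariate-adjusted linear and proportional-odds association models
    with Bonferroni families, and profiles size-exclusion
    chromatography fractions (percent of total, peak calling,
    molecular-weight calibration). A synthetic-data module generates
    every input type with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
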