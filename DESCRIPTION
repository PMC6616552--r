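Package: astromicro
Title: Longitudinal Analysis of Astronaut and Spacecraft Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for longitudinal 16S rRNA OTU-table studies of
    spaceflight crews and their built environment. Provides OTU-table readers
    (TSV, mothur shared, BIOM-JSON), control-based contaminant removal and
    low-support filtering, prevalence-based core and resident microbiome
    rules, alpha diversity and rarefied richness, weighted and unweighted
    Bray-Curtis dissimilarity with PCoA and stratified PERMANOVA,
    mission-stage distance designs with mixed-model contrasts, inter-subject
    convergence tests with coefficient-of-variation attribution, cytokine
    stage contrasts with left-censored immunoassay regression, and a
    within-subject Somers' D association screen between discretized OTU
    abundances and cytokine levels with delete-one-subject jackknife
    standard errors. Includes a Dirichlet-multinomial synthetic cohort
    generator that emulates the longitudinal mission design for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    permute,
    lme4,
    survival,
    biomformat,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
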