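Package: alfaselect
Title: PCA-Based Composite Selection Index for Multi-Trait Alfalfa Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and validating a principal-component-based
    composite selection index over six yield-related agronomic traits in
    alfalfa (Medicago sativa L.) hybrid breeding: trait-table I/O and
    validation, descriptive statistics, Pearson correlations, t-tests, one-way
    ANOVA with Duncan's multiple range test and compact letter displays,
    correlation-matrix PCA with Kaiser retention, variance-weighted index
    construction, elite-individual selection, intergenerational comparison
    metrics, and a seeded multivariate-normal breeding-population simulator
    with a breeder's-equation response model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
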