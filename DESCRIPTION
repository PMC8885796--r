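Package: tilpatterns
Title: Immunoarchitectural Patterns of Tumor-Infiltrating Lymphocytes on
    Whole-Slide Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial distribution of tumor-infiltrating
    lymphocytes (TILs) on annotated breast-cancer whole-slide images.
    Builds tumor-center, invasive-margin and para-tumor compartments from
    region polygons, computes lymphatic-nucleus-area-to-stromal-area
    ratios per compartment, classifies each case into one of five
    immunoarchitectural patterns (IP1-IP5) by fixed ratio cut-offs, and
    provides the cohort statistics used to relate the patterns to
    clinicopathological covariates and disease-free survival:
    chi-square (Pearson and linear-by-linear trend), Fisher exact,
    Kruskal-Wallis, Mann-Whitney with SPSS-style z, Kaplan-Meier,
    weighted log-rank (log-rank, Breslow, Tarone-Ware) and Cox
    proportional hazards. A synthetic-cohort generator produces virtual
    slides and clinicopathological tables with configurable pattern
    mixtures so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
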