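Package: inflammage
Title: Dietary Inflammation Scores and Blood-Biomarker Biological Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the association between the inflammatory potential
    of diet and biological aging in epidemiological cohorts. Implements the
    Dietary Inflammatory Index (DII), its energy-adjusted variant (E-DII) and
    the whole-food Dietary Inflammation Score (DIS) over per-subject intake
    tables with pluggable reference databases; trains a neural-network
    biological-age clock on circulating biomarkers and computes delta-age
    (biological minus chronological age) with permutation feature importance;
    applies cohort eligibility filters and builds quartile descriptive tables;
    and fits multiply-imputed, Rubin-pooled linear models of delta-age on the
    standardized scores, with subgroup, interaction and sensitivity analyses.
    A synthetic cohort generator with a configurable ground-truth
    diet-inflammation effect makes every stage testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
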