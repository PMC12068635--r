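Package: cohortforge
Title: Self-Service Cohort Selection for Prospective Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated cohort-selection engine for prospective cohort
    studies. Turns a declarative selection specification (endpoint,
    start of follow-up, censoring rules, covariate selectors) into an
    analysis-ready time-to-event or cross-sectional dataset together with
    a data dictionary, value-label formats, reader scripts for SAS and R,
    and a selection summary, all versioned into a read-only data
    directory. Endpoints are resolved from ICD-O-3 coded cancer events,
    ICD coded causes of death, and hospitalization-based computable
    phenotypes with length-of-stay and admission-count requirements.
    A seeded synthetic cohort generator emulates the structure of a
    large women's prospective cohort (baseline plus up to five follow-up
    surveys, ~1200 survey covariates, linked cancer, hospitalization and
    mortality events, missing-by-design survey gaps) so the whole engine
    is exercisable without access to any controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
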