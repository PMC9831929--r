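Package: maculahdp
Title: Sequential Macular Thickness Analysis in Hypertensive Disorders of Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequential ETDRS-grid macular thickness
    measurements through pregnancy. Implements a contiguity-based interval
    change-detection rule (directionally identical differences of at least
    4 micrometres in three or more contiguous grid sectors) with
    empirical-null calibration from same-encounter replicate scan pairs,
    longitudinal classification of eyes and participants (early gestational
    thinning, loss of thinning, hypoperfusion events), hierarchical
    mixed-effects estimation of mean thickness change from the non-pregnant
    baseline across gestational intervals, mean arterial pressure summaries
    anchored to retinal events, and a seeded synthetic cohort generator
    emulating the statistical structure of a prospective repeated-measures
    study of hypertensive disorders of pregnancy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
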