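Package: ctlar
Title: Projected Lifetime Cancer Risk from National CT Utilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Projects lifetime radiation-induced cancer incidence from
    national computed tomography (CT) utilization. Generates synthetic
    exam-level CT registry data with per-organ absorbed doses, summarizes
    examinations into sex by age-group by CT-category strata, scales counts
    to national volume with end-of-life exclusion, computes per-examination
    lifetime attributable risk (LAR) using BEIR VII-style excess relative
    and absolute risk models with life-table competing-risk survival,
    propagates parameter uncertainty by Latin hypercube sampling, and
    reports projected cancer counts with 90% uncertainty limits alongside
    a suite of sensitivity scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
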