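Package: ossindent
Title: Bone Nanoindentation Reduction, Histomorphometry Indices, and
    Case-Control Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing Berkovich nanoindentation force-depth curves
    on bone tissue to elastic modulus, contact hardness, resistance to plastic
    deformation, and elastic/plastic indentation energies via Oliver-Pharr
    contact mechanics; for deriving ASBMR structural, static, and
    tetracycline-based dynamic bone histomorphometry indices on the
    cancellous, intracortical, and endosteal envelopes; and for nested
    case-control statistics (group summaries, two-sample t tests, and odds
    ratios from clustered logistic regression fitted by generalized
    estimating equations). Includes a seeded synthetic-data generator that
    simulates indentation curves from an elastic-plastic conical contact
    model with creep, thermal drift, and noise, plus cohort and
    histomorphometry tables with subject-level clustering, so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    readr
Suggests:
    broom,
    optparse,
    sandwich,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
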