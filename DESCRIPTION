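Package: migcost
Title: Cost-of-Illness Modelling of Migraine in Working Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic decision-analytic cost-of-illness pipeline for
    migraine in an employed population, built around a micro-costing model of
    direct healthcare costs (outpatient consultations, diagnostic tests,
    medicines, complementary therapies) and human-capital indirect costs
    (wage-valued lost workdays), evaluated from the healthcare-system,
    employer, and societal perspectives. Includes a synthetic survey generator
    emulating a HARDSHIP-style headache survey, utilisation summary tables
    with episodic-versus-chronic migraine comparisons, deterministic point
    costing, one-way (tornado) sensitivity analysis, and Monte Carlo
    probabilistic sensitivity analysis, plus a reproducible reporting
    pipeline driven by a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
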