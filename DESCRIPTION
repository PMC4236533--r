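Package: fdslink
Title: Formulary Decision Support, Copayment, and Adherence in Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how electronic prescribing with formulary
    decision support (FDS) shifts prescribing toward preferred formulary
    tiers, and how that shift propagates to patient copayments and to
    medication adherence measured as the 180-day proportion of days covered
    (PDC). Provides a seeded synthetic pharmacy-claims generator with known
    ground truth; a new-user cohort builder (minimum days-supplied filter,
    180-day same-class washout, synthetic control activation dates, exposure
    period labelling); an interval-based PDC engine with a stockpiling
    convention; the three statistical links (clustered difference-in-
    differences logistic regression fitted by generalized estimating
    equations with exchangeable working correlation, a tier-to-copayment
    linear model on Box-Cox transformed copayments, and a linear mixed model
    of PDC on transformed copayment with prescriber random intercepts);
    backward model selection under QIC/AIC; and a chained projection
    calculator that combines the three links, or external benchmark
    copayment and cost-sharing-elasticity constants, into expected
    copayment and adherence effects.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
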