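Package: mouthwashCEA
Title: Cost-Effectiveness of Preoperative Chlorhexidine Mouthwash for
    Postoperative Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing two-dose
    preoperative chlorhexidine mouthwash with no mouthwash for the prevention
    of postoperative pneumonia after abdominal surgery, from a South African
    healthcare provider perspective over a 30-day horizon. Implements the
    pathway decision tree with cohort expected values, a COVID-19 scenario
    overlay, deterministic sensitivity analysis (relative-risk-reduction
    sweeps, one-way parameter variation, dominance break-off threshold search,
    extreme scenarios), probabilistic sensitivity analysis with beta/gamma
    parameter uncertainty, cost-effectiveness acceptability curves and net
    monetary benefit, market-basket/PPP currency transfer utilities, and a
    patient-level microsimulation oracle with synthetic cohort generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
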