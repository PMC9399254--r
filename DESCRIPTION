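Package: oatrisk
Title: Overdose Risk During and After Opioid Agonist Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pharmacoepidemiology pipeline for studying non-fatal
    overdose risk among recipients of opioid agonist treatment (methadone or
    buprenorphine) in linked primary-care, hospitalisation and mortality
    records. Reconstructs treatment episodes from prescription issue dates
    under supply-duration, gap and overlap rules; splits follow-up into
    time-varying risk windows around treatment initiation and cessation;
    ascertains overdose outcomes against configurable clinical code lists;
    balances treatment modalities with stabilised inverse-probability-of-
    treatment weights; estimates crude, adjusted and weighted rate ratios
    (Poisson or negative binomial with person-time offsets and cluster-robust
    variance) and first-event hazard ratios; and quantifies unmeasured
    confounding with E-values. Ships a synthetic-cohort generator with known
    ground truth for validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
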