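Package: pnrct
Title: Simulation and Mixed-Model Analysis of Partially Nested Randomised
    Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing two-arm partially nested
    randomised controlled trials (pnRCTs) with continuous outcomes, where
    participant outcomes are clustered (for example by therapy group or
    care provider) in the intervention arm only. Provides a seeded trial
    data generator, the three conventions for coding cluster labels in the
    non-clustered control arm (singleton clusters, one large cluster,
    pseudo clusters), restricted maximum likelihood (REML) fitting of
    linear, fully clustered, and partially nested homoscedastic and
    heteroscedastic mixed-effects models via closed-form block
    compound-symmetry algebra, Satterthwaite degrees of freedom for the
    intervention effect, intracluster correlation estimation, and a
    scenario-grid Monte Carlo study runner computing Type I error, power,
    coverage, bias, mean square error and ICC recovery with Monte Carlo
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    nlme,
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
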