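Package: qtcompete
Title: Joint Concentration-QTc Modelling of Bedaquiline, Pretomanid, and
    Clofazimine with Competitive Drug Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population concentration-QTc (PK/PD) modelling for the
    QT-prolonging antituberculosis drugs bedaquiline (through its
    N-desmethyl metabolite BDQM2), pretomanid, and clofazimine.
    Implements a structural QTc model with heart-rate correction, a
    three-oscillator circadian baseline, an exponential secular trend on
    treatment, and a shared-Emax competitive-interaction drug effect in
    which companion drugs shift each other's EC50; fits it by
    Laplace-approximate maximum marginal likelihood with optional normal
    prior penalties (via 'TMB'); generates virtual
    early-bactericidal-activity trials with matched ECG/PK sampling for
    simulation studies; and runs Monte-Carlo dosing-regimen simulations
    summarised against ICH E14 QTc thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    TMB,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
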