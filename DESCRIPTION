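Package: ayapbpk
Title: Whole-Body PBPK Simulation of Ayahuasca Alkaloid and SSRI
    Drug-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) modelling of the
    ayahuasca alkaloids N,N-dimethyltryptamine (DMT) and harmine and their
    pharmacokinetic interactions with the selective serotonin reuptake
    inhibitors fluoxetine (with its metabolite norfluoxetine) and
    paroxetine.  Implements a whole-body perfusion-limited compartment
    model with oral absorption, gut-wall and hepatic first-pass
    metabolism, tissue partition coefficient prediction (Rodgers-Rowland
    and Schmitt-type methods), reversible MAO-A and competitive CYP
    inhibition, mechanism-based CYP2D6 inactivation with enzyme turnover,
    virtual-population sampling, non-compartmental analysis, mean-fold-error
    model qualification, DDI ratio classification, parameter estimation
    against observed plasma profiles, local sensitivity analysis, and a
    synthetic clinical-trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
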