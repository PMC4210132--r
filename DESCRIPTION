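Package: eicosim
Title: Kinetic Modelling of Arachidonic Acid and Eicosanoid Metabolism in
    DDC-Treated Mouse Liver
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A twelve-reaction kinetic model of hepatic arachidonic acid (AA)
    and eicosanoid metabolism (the prostaglandin, 5-lipoxygenase and
    15-lipoxygenase branches), initialized from transcriptomics and
    reverse-phase protein array fold changes of three mouse strains (A/J,
    C57BL/6J, PWD/PhJ) fed a DDC-supplemented steatohepatitis-inducing diet.
    Provides steady-state simulation of control versus DDC-treated
    conditions, fold-change prediction and classification, genetic-algorithm
    calibration of kinetic parameters against measured metabolite
    concentrations, combinatorial enzyme-reversion and in-silico
    drug-inhibition screens, expression-to-activity mapping with an
    isoenzyme-selection rule, synthetic-data generation for end-to-end
    testing, and SBML Level 3 model exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
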