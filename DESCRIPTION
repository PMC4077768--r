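Package: iltol
Title: Mechanistic Modelling of Ionic-Liquid Tolerance Under Efflux-Pump
    Promoter Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled kinetic model of Escherichia coli growth, substrate
    consumption, efflux-pump expression and intracellular ionic-liquid (IL)
    accumulation, for comparing promoter strategies (promoterless,
    constitutive, IL-responsive) that drive a heterologous IL export pump.
    Includes an adaptive ODE simulator with a reactor-level IL mass balance,
    a serial-passage competition simulator, parameter-calibration routines
    (growth kinetics, IL toxicity, pump burden, promoter induction
    parameters), promoter-screening analytics (fold-change/p-value
    differential-expression filtering, 2^-ddCt qPCR quantification, SRM
    peptide peak-area ratios, induction-tier ranking) and seeded synthetic
    data generators for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
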