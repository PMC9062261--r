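Package: cardiomyosim
Title: Kinetic Modeling of Cardiomyocyte Energy Metabolism in Ischemia
    and Reperfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-compartment kinetic model of cardiomyocyte energy
    metabolism coupling glycolysis, glycogen handling, lactate dynamics and
    cytosolic ATP buffering to mitochondrial oxidative phosphorylation
    (phenomenological TCA dehydrogenase, respiratory complexes I/III/IV,
    F1F0-ATP synthase, adenine nucleotide translocase, proton leak and ion
    transporters) across five compartments.  Provides stiff ODE time-course
    simulation of ischemia/reperfusion oxygen protocols (single and two-step
    reperfusion), physiological steady-state search, finite-difference
    metabolic sensitivity analysis, and scalar injury-surrogate readouts
    (ATP depletion/recovery times, membrane-potential plateau and spike,
    reverse electron transport at complex I, complex-III rate spike), with
    CSV/JSON/SBML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
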