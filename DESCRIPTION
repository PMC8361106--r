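Package: kgtrace
Title: Stable-Isotope Tracing, Isotopologue Correction, and Ester
    Hydrolysis Kinetics for Alpha-Ketoglutarate Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative stable-isotope tracing metabolomics
    centred on alpha-ketoglutarate (KG) and its cell-permeable esters.
    Implements molecular-formula mass calculus including methoxime/TBDMS
    GC-MS derivatives and diagnostic fragment ions; MS1 feature detection
    and accurate-mass/retention-time library quantitation with blank
    correction for centroided LC-MS peak tables; natural-isotope-abundance
    correction of mass isotopologue distributions by non-negative least
    squares; mole-percent-enrichment (MPE) and stable-isotope dilution
    estimates of carbon source contributions, including compartmentalized
    2-hydroxyglutarate reporter readouts; internal-standard absolute
    quantitation; consecutive first-order models of di-ester hydrolysis
    with least-squares rate fitting and a buffer/polyprotic-acid pH
    equilibrium model; and ground-truth synthetic-data generators for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
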