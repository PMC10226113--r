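Package: fpmono
Title: Electrolyte Adsorption on Insoluble Monolayers from Compression
    Isotherms and Spreading Pressures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic processing of Langmuir-trough compression
    isotherms of insoluble amphiphile (lipid) monolayers spread on
    electrolyte solutions.  Implements the Frumkin-Pankratov method: the
    equilibrium spread monolayer fixes an electrolyte-independent
    reference chemical potential, so that integrating area-per-molecule
    over surface pressure yields the amphiphile chemical-potential change
    per isotherm, and cross-concentration differentiation at constant
    chemical potential or constant surface pressure yields the
    monolayer-induced electrolyte adsorption.  Includes a spreading-point
    estimate, a consistency check between the two routes, a
    complexation/excluded-volume adsorption model with least-squares
    fitting, and a Gibbs-Duhem-consistent synthetic isotherm generator
    with closed-form adsorption fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
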