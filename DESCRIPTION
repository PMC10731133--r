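Package: osteomech
Title: Micromechanical Analysis of Bone Extracellular Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative micromechanics of cortical bone extracellular
    matrix. Converts microtensile force-displacement records to
    stress-strain curves and extracts loading modulus, ultimate stress and
    failure strain; analyses polarization-resolved Raman line scans for
    mineralized collagen fiber orientation and degree of mineralization;
    performs Oliver-Pharr analysis of trapezoidal nanoindentation records;
    computes anisotropic indentation moduli of transverse isotropic
    half-spaces by Barnett-Lothe surface Green's function integration and
    fits a combined fiber-angle/mineralization model of the indentation
    modulus; extracts tissue mineral density from calibrated micro-CT
    volumes; and provides mixed-effect group statistics with
    likelihood-ratio tests and Dunn-Holm post hoc comparisons. A synthetic
    cohort generator emulating healthy and osteogenesis imperfecta iliac
    crest biopsies makes the complete pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    minpack.lm,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
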