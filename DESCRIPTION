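Package: gastrudyn
Title: Signaling Dynamics and Fate Patterning in Micropatterned Human
    Gastruloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study self-organized germ-layer patterning of
    BMP4-treated micropatterned human embryonic stem cell colonies
    (gastruloids). Provides reaction-diffusion simulators for a generic
    activator-inhibitor system and for a BMP-driven WNT/NODAL signaling
    cascade on arbitrary colony geometries, linear stability (Turing)
    analysis with dispersion relations, phenomenological fate-territory
    prediction, quantification of radial intensity profiles and
    signaling wave fronts from colony images, cell-track statistics,
    and the gene-set selection procedures used for differential
    expression analysis of the extra-embryonic edge fate. A synthetic
    data module generates image stacks, wave profile series, cell
    tracks and expression matrices with known ground truth so every
    analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
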