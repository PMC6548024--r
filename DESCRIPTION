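Package: leafmorph
Title: Simulation and Cell-Resolution Quantification of Leaf Margin Morphogenesis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how leaf margin patterning and bulk tissue growth
    interact to shape simple (serrated) versus dissected (leaflet-bearing)
    leaves. Provides a geometric simulator of one-dimensional margin
    development (growth-driven convergence-point patterning, a basipetally
    receding differentiation line, and localized basal growth repression), a
    two-dimensional growing-tissue model coupling an auxin-PIN1-CUC2 margin
    reaction module to tissue-dependent specified growth and elastic
    relaxation, cell-resolution growth quantification for segmented time-lapse
    tessellations (area extension, growth anisotropy tensors, lobeyness,
    lineage algebra, region fate maps, growth-alignment graphs, protrusion
    shape metrics), and a synthetic time-lapse generator with known ground
    truth for validating every quantification stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
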