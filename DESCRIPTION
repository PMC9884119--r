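Package: blastocyto
Title: Nucleus-Level Image Cytometry for Mouse Blastocyst Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies per-nucleus marker levels in multi-channel confocal
    z-stacks of preimplantation mouse embryos. Nuclei are segmented in 3D by
    per-slice 2D detection followed by z-linking, measured for position,
    volume, per-channel mean intensity and integrated density, filtered by
    DAPI-signal and volume quality controls, and compared across embryonic
    stages (E3.5, E4.5, diapause) with rank-based statistics. Includes
    flow-cytometry-style threshold and polygon gating in co-expression space,
    spatial "in silico embryo" reconstruction from nucleus centroids, and a
    ground-truthed synthetic blastocyst stack generator so the whole pipeline
    can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
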