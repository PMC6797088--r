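Package: strandscan
Title: Detection of Stranded Whales in Very High Resolution Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting stranded whale carcasses in very high
    resolution multispectral satellite imagery. Provides Gram-Schmidt
    pan-sharpening of a multispectral/panchromatic image pair, NDWI-based
    water masking with a metric coastal buffer, Spectral Angle Mapper (SAM)
    target detection with target and exclusion signatures, connected-component
    grouping of flagged pixels into whale-like objects with morphometric
    confidence classes, and evaluation of detections against survey or truth
    locations (errors of commission and omission stratified by match
    likelihood). A synthetic coastal scene generator with ground-truth
    annotations emulates the WorldView2 band structure and the heterogeneous
    spectra of decomposing carcasses, so the whole pipeline can be exercised
    and validated without proprietary imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
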