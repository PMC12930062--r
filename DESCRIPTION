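Package: synaptoscope
Title: Synaptic Puncta Detection, Volumetric Colocalization and
    Sensory-Learning Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection of pre- and post-synaptic protein puncta in
    dual-channel confocal z-stacks (intensity normalization, white top-hat
    background removal, adaptive Wiener denoising, multi-scale Laplacian-of-
    Gaussian blob detection, median mask refinement and size/intensity
    quality filtering), object-based volumetric colocalization of the two
    channels, per-mouse/region aggregation with ROUT robust outlier
    flagging, and trials/errors-to-criterion scoring of complex
    sensory-learning-task (attentional set-shifting) session logs. Includes
    ground-truth synthetic generators for dual-channel puncta stacks and
    behavioral choice sequences, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Neuroscience, Visualization
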