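Package: marmobehav
Title: Home-Cage Behavioral Quantification for Marmoset Stroke Models from
    Depth-Camera Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies home-cage locomotor behavior of a common marmoset
    (Callithrix jacchus) from depth-camera recordings, as used to follow
    recovery in photothrombotic stroke models. Provides a synthetic-data
    module that simulates pre- and post-stroke trajectories and renders
    depth-frame recordings; a tracker (background model, foreground
    segmentation, largest-blob centroid, gap-aware linking); daily locomotor
    metrics (distance traveled, median moving speed, activity time,
    jump/climb frames, trajectory range); the 4-sign observational
    neurological score; and the statistics relating them
    (baseline-ratio normalization, 3-day binned means with SEM, paired
    pre/post t-tests, Spearman rank correlation of metrics against scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
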