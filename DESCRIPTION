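Package: germtrack
Title: Seed-Level Germination Phenotyping and Vigor Scoring from
    Time-Lapse Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies seed germination at the level of individual seeds
    from overhead time-lapse image series on germination paper. Root tips
    are tracked through time as temporal directed graphs over binary-mask
    skeletons, with 3- and 4-arm root intersections resolved by
    vector-angle pairing; static and dynamic traits (morphology, colour,
    radicle length and growth rate, phase and event times including
    coleoptile emergence and chloroplast biogenesis via the excess-green
    index) are derived per seed and per lot; genotypes are grouped into
    germination-speed classes, scored for uniformity of event times, and
    combined into a speed-by-uniformity vigor matrix. Includes a
    ground-truthed synthetic germination simulator so the full pipeline is
    testable without any image archive, plus a classical colour-threshold
    segmentation fallback for label maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
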