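Package: meiotrace
Title: 4D Chromosome Trajectory Analysis for Mouse Oocyte Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 4D (3D + time) chromosome trajectories in
    meiosis I mouse oocytes: reading Vaa3D-style marker annotations, voxel to
    micron conversion and tracing-error quality control, per-frame spindle
    ellipsoid fitting, PCA-based equator-plane estimation and spindle-frame
    alignment, axial/radial/tangential speed decomposition, four-step
    segmentation of the recording, a two-layer GRU recurrent classifier that
    sorts distance-to-equator sequences into retracing, congressing and
    quasi-static trajectories, and group statistics (one-sided Mann-Whitney,
    Fisher's exact test, Benjamini-Hochberg adjustment). Includes a seeded
    synthetic oocyte simulator reproducing wild-type kinematics and
    kinesin-knockdown phenotypes so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
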