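Package: sptnano
Title: Mobility States and Nanoscale Clustering from Single-Particle
    Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-particle tracking photoactivated
    localization microscopy (sptPALM) trajectories of membrane molecules
    in neuronal dendrites. Provides time-averaged mean-square-displacement
    (MSD) diffusion estimation with immobile/mobile classification,
    moment-scaling-spectrum (MSS) motion-type analysis, global fitting of
    a three-diffusive-state displacement cumulative-distribution model
    across cells, Voronoi-tessellation-based nanodomain (nanocluster)
    detection, spine/shaft compartment assignment from polygon ROIs, a
    per-cell statistical comparison layer, and a ground-truth-labelled
    Brownian-dynamics simulator of multi-state diffusion with nanodomain
    trapping for end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deldir,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    polyclip,
    sp,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
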