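Package: thtrack
Title: Simulation and Analysis of DNA-Mediated Fluorophore Exchange for
    Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-particle tracking with transiently binding,
    continuously exchanging DNA-based fluorescent labels ("tracking handles")
    and their photobleaching-limited single-dye controls. Provides an exact
    stochastic (Gillespie) simulator of imager association, dissociation and
    photobleaching on a multi-site handle; synthetic TIRF movie rendering of
    immobilized and membrane-diffusing particles with Poisson shot noise;
    spot detection and integrated-Gaussian localization; nearest-neighbour
    trajectory linking; trajectories-per-particle (TPP) survival statistics
    with half-life estimation; per-trajectory diffusion constants by
    iterative mean-squared-displacement fitting; and subtrajectory
    motion-change analysis against the theoretical uncertainty limit of
    short-segment diffusion estimates.
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
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
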