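Package: prosodent
Title: Delta-Band Neural Entrainment to Prosodic Contours: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of delta-band magnetoencephalography (MEG)
    responses to repetitive prosodic (pitch) contours. Provides harmonic
    resynthesis of fundamental-frequency tracks into delexicalized audio
    contours, trial-timeline generation for an entrainment paradigm with slow
    (0.6 Hz) and fast (0.9 Hz) contour cycles, a synthetic multichannel MEG
    generator with a toy forward model and planted entrained, sustained and
    omission-evoked sources, Hann-tapered zero-padded spectral estimation of
    pitch-MEG coherence and power on a 0.1 Hz grid, cluster-based sign-flip
    permutation tests over a sensor neighborhood graph, the rate-specific
    response (RSR) index, omission evoked-field contrasts, and DICS/LCMV
    beamforming with common spatial filters on the toy source space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
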