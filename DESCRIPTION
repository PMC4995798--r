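Package: nanodose
Title: In Vitro Nanoparticle Dosimetry from DLS, CLS and UV-Vis Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the cellular dose of nanoparticles in in vitro
    exposure experiments. Combines dynamic light scattering (DLS) and
    centrifugal liquid sedimentation (CLS) measurements to derive the apparent
    mass density of nanoparticle-protein complexes, computes diffusion and
    gravitational sedimentation transport descriptors (transport times, Peclet
    number) to classify the dominant transport mode in a culture well, and
    converts UV-vis supernatant absorbance spectra into deposited fractions
    and per-cell particle numbers over multi-day exposures. A seeded synthetic
    data module (surface-plasmon-resonance spectra, disc-centrifuge detector
    traces, and a one-dimensional finite-volume sedimentation-diffusion well
    simulator with a saturable cell-affinity boundary) generates every input
    the pipeline consumes, so all stages are testable from known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
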