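Package: ciliaphys
Title: Electrophysiology, Calcium Imaging and Motility Analysis of Ependymal Motile Cilia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of motile cilia on ependymal cells:
    an equivalent-circuit model of patch-clamp access through a ciliary
    cable (membrane capacitance, series resistance, cable resistance,
    voltage-gated channel counts, Nernst potentials), capacitive-transient
    and leak-subtraction analysis of voltage-clamp sweeps, single-channel
    amplitude histograms and open probability, ratiometric GCaMP6s/mCherry
    calcium calibration with bleed-through correction and Hill-equation
    inversion, and image-based motility quantification (kymograph beat
    frequency, calcium front velocity from line scans, bead-tracking
    velocimetry). Every analysis stage is paired with a seeded synthetic-data
    generator carrying machine-readable ground truth, so the full pipeline
    can be validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
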