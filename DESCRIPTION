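Package: mucometry
Title: Quantitative Image Analysis of Mucociliary Function and Lung Fibrosis Assays
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tested, reusable implementations of the quantitative assays used to
    characterize mucociliary dysfunction and pulmonary fibrosis in mouse models of
    mucin (Muc5b) overexpression: passive microbead microrheology with
    overlapping-window mean squared displacement and linear drift correction;
    micro-optical coherence tomography functional metrics (airway surface liquid and
    periciliary layer depths, ciliary beat frequency by Fourier analysis, mucociliary
    transport rate by kymograph streak orientation); second-harmonic-generation
    fibrillar collagen area fractions with least chi-square Gaussian mixture histogram
    statistics and stereological estimators (Cavalieri volumes, point counting); and
    plate/count endpoint assays (standard-curve interpolation, reduction kinetics,
    acute endogenous clearance, survival chi-square, stress-sweep viscosity).
    A seeded synthetic-data module generates every input with known ground truth so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
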