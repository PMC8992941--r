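Package: ebcal
Title: Electron Beam Output Calibration for Clinical Linacs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes absorbed dose to water per monitor unit for clinical
    electron beams from raw ionization-chamber readings. Implements the
    standard TRS-398 reference dosimetry procedure (table-interpolated
    beam-quality factor kQ,Qo, chamber shifted 0.5*rcyl beyond the reference
    depth) and a modified calibration that uses fitted beam-quality factors
    kQ' (power-law for cylindrical chambers, exponential for parallel-plate
    chambers) with the chamber positioned at the reference depth, and
    compares the two protocols against the +/-2 percent clinical tolerance.
    Includes reading corrections for temperature/pressure, polarity, ion
    recombination and electrometer calibration, R50 extraction from depth-
    dose curves, and a synthetic-session generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
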