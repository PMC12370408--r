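Package: targetdeg
Title: Dosimetric Detection of Linac Photon Target Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting photon-target degradation on
    C-series linear accelerators from water-phantom dose grids.  Reads and
    writes DOSXYZnrc '3ddose' files, extracts percentage depth dose and
    off-axis profiles, and computes the quality-assurance metrics used to
    flag a degrading bremsstrahlung target: beam output with
    monitor-chamber and jaw-backscatter corrections, PDD20,10 beam quality,
    maximum profile deviation and flatness, relative output and wedge
    factors, and 2-D gamma-index comparisons of planar doses.  A calibrated
    analytic beam generator emulates nominal and degraded 6 MV fields so
    the whole pipeline runs at desk scale without Monte Carlo transport.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
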