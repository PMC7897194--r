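Package: bqtaler
Title: Biquadratic Time-Averaging Local-Elevation 3J-Coupling Restraining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for restraining molecular torsion angles against measured
    three-bond scalar (3J) NMR couplings using a biquadratic, time-averaged,
    local-elevation penalty (BQ-TA-LER). Provides Karplus-curve evaluation and
    multi-valued inversion for backbone phi and side-chain chi1 couplings, the
    adaptive restraining potential with exponentially damped coupling averages
    and a periodic Gaussian local-elevation grid, a stochastic torsional
    dynamics sampler to exercise the method at desk scale, and analysis of
    NMR observables: coupling statistics, deviation histograms, consensus
    stereo-specific assignment, S2 order parameters, r^-3 averaged NOE
    distances and hydrogen-bond occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
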