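Package: photoacid
Title: Excited-State Proton Transfer Kinetics of Photoacids by
    Diffusion Modelling and TCSPC Reconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the photoprotolytic cycle of
    naphthol-family photoacids free in solution and bound to amyloid
    fibrils. Solves the spherically-symmetric Debye-Smoluchowski
    equation for reversible geminate proton recombination with a
    back-reaction boundary condition and fractional diffusion
    dimensionality, computes Debye radii, synthesises and fits
    time-correlated single photon counting (TCSPC) decays by
    instrument-response reconvolution (full diffusion model and
    multi-exponential), decomposes steady-state emission spectra into
    ROH*/RO-* bands, and tracks amyloidogenesis through the band
    ratio. Includes closed-form and Brownian-dynamics oracles for
    solver validation and a synthetic-data module emulating the
    measurement conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
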