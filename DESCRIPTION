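Package: tauchaperone
Title: Kinetic Dissection of Chaperone-Mediated Suppression of Tau Amyloid Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how molecular chaperones (HSPB1, DNAJA2,
    DNAJB1) suppress tau amyloid formation. Implements a
    nucleation/saturating-elongation/fragmentation kinetic model of fibril
    growth with a compiled adaptive ODE simulator, conversion of Thioflavin-T
    plate-reader traces to fibril mass concentration, half-time extraction and
    scaling-exponent analysis, a two-step global fit (reduced rates from
    unseeded data under the kp = 1 convention, absolute rates from seeded
    data), constrained refits that identify which microscopic rate each
    chaperone perturbs, seed length estimation from dynamic light scattering
    via Stokes-Einstein and prolate-ellipsoid friction, one-site binding fits
    of fluorescence anisotropy titrations, NMR chemical-shift-perturbation and
    intensity-ratio binding maps, and a synthetic-data generator that emulates
    every input so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
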