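Package: choanopump
Title: Stokes-Flow Simulation of Sponge Choanocyte-Chamber Pumping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spherical choanocyte chamber of leuconoid sponges as a
    low-Reynolds-number pump: many flagella beating inside a no-slip spherical
    shell with a single large outlet (apopyle), many small inlets (prosopyles),
    a concentric reticulum shell and a cone-cell ring. The resistance problem
    is solved with regularized Stokeslets (collocation on surface elements and
    slender-body node distributions along flagella), yielding the outlet flow
    rate, internal pressure, flagellar work rate and mechanical pumping
    efficiency over a beat cycle. Also provides a coarse-grained point-force
    chamber model, morphometric calculations linking model parameters to
    measured chambers across sponge species, unit conversions, synthetic
    morphometry and waveform-track generators, and a parameter-sweep pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
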