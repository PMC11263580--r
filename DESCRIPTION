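Package: porejam
Title: Soft Jamming of Viral Particles in Nanopores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward model and inference tools for flow-driven transport of
    viral particles through cylindrical nanopores. Implements Poiseuille
    nanochannel hydraulics, the soft-jamming translocation model in which the
    passage time decomposes into a Langmuir-gated entry time and an
    adhesion-advection transit time, the suction-model DNA probe of clog
    geometry, weighted nonlinear estimation of the interaction parameters
    (wall on-rate, clog off-rate, clog dissociation constant), a master-curve
    collapse diagnostic, and a seeded synthetic-data generator emulating
    zero-mode-waveguide translocation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
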