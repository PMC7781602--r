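Package: relaywave
Title: Diffusive Signaling Relays: Wave Propagation, Initiation, and
    Chemotactic Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling diffusive signaling relays, in which cells
    that sense a diffusible molecule above a threshold concentration join in
    emitting the same molecule, producing self-propagating trigger waves.
    Implements closed-form asymptotic wave speeds and comoving concentration
    profiles for matched and mismatched cell/diffusion dimensionalities,
    Green's-function quadrature of concentration fields from emitting
    colonies and moving activation fronts, wave-initiation times and
    critical colony sizes, a self-consistent information-front propagator,
    an independent finite-volume reaction-diffusion solver with Heaviside or
    Hill activation, and a neutrophil-swarming application layer (front
    prediction, relay versus simple-diffusion fitting, and chemotactic
    gradient comparison) with a synthetic chemotactic-index generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
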