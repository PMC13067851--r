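Package: spiralctl
Title: Closed-Loop Optogenetic Detection and Termination of Cardiac Spiral Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An in-silico platform for smart optogenetic control of cardiac
    arrhythmias in cultured monolayers. Simulates spiral-wave (rotor) activity
    in a heterogeneous circular cardiac monolayer with a monodomain
    reaction-diffusion model, detects phase singularities by topological
    charge, generates labelled synthetic optical-voltage-mapping movies,
    trains a shallow convolutional neural network to localize spiral cores
    from five-frame windows, and closes the loop: a virtual camera feeds the
    detector, a trigger rule selects the core, and a virtual micro-LED matrix
    projects a light line from the core to the nearest boundary to terminate
    reentry through channelrhodopsin-mediated depolarization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
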