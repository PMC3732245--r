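Package: rekam
Title: Reconsolidating Kernel Associative Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attractor neural memory whose stored patterns live in a
    kernel-induced feature space (a kernel associative memory), together
    with a model of memory reconsolidation: recalled attractors are moved
    toward new stimuli either exactly, along geodesics of the Riemannian
    manifold of memory states, or approximately, along straight lines in
    coordinate space.  Includes controllable attraction-basin radii
    (extinction of fear memories), continuous-time firing-rate recall
    dynamics equivalent to the pseudoinverse Hopfield network for the
    scalar-product kernel, and synthetic-stimulus simulations of three
    behavioral reconsolidation effects: list-learning intrusions,
    extinction, and incremental tracking of gradually rotating images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
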