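Package: spikemee
Title: Recurrent Spiking Networks Trained with a Restricted Minimum Error
    Entropy Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of recurrent spiking neural networks
    built from three-compartment neurons with adaptive firing thresholds.
    Networks are trained by backpropagation through time with a surrogate
    spike derivative, under information-theoretic loss functions: kernel
    estimates of Renyi quadratic entropy, quantized and restricted
    minimum-error-entropy (RMEE) information potentials with half-quadratic
    optimization, and a combined RMEE plus cross-entropy criterion.
    Includes sparse sign-preserving connectivity with deep rewiring, a
    clipped-surrogate policy-gradient trainer for reward-based learning,
    and generators for three synthetic benchmarks: a store-recall working
    memory task, noisy sequential glyph classification, and a 2D
    navigation arena with Gaussian population rate coding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
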