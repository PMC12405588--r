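Package: hunchcast
Title: Feeding-State-Dependent Action Selection in Drosophila Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the choice between the protective Hunch and
    the exploratory Head Cast in Drosophila larvae responding to an air puff,
    and how the feeding state biases that choice. Implements a
    connectome-constrained rate model of the seven-population decision
    circuit (mechanosensory input, Basin-1/2 projection neurons, reciprocally
    connected feedforward inhibitory interneurons iLNa/iLNb, and feedback
    interneurons Handle-a/b) with neuromodulation and silencing variants,
    steady-state classification into coactive/monoactive attractors, and
    phase diagrams over modulation parameters; a kinematic pipeline for
    11-point midline tracks (resampling, filtering, posture and speed
    features, stride/run/pause annotation, path metrics); frame-level action
    classification with regularisation and Hunch/Static-Bend rules;
    behavioural statistics (action probabilities, the Theta resampling test,
    generalized likelihood-ratio transition tests, maximum mean discrepancy
    permutation tests, fluorescence response metrics, preference index); and
    a seed-deterministic synthetic-track generator with ground-truth labels
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    signal,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
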