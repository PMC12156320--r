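Package: ureweight
Title: Umbrella Refinement of Conformational Ensembles Against Experimental Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-entropy/Bayesian reweighting of conformational ensembles
    against ensemble-averaged experimental observables (NMR chemical shifts,
    three-bond J couplings, NOE upper distance bounds). Instead of optimizing
    one statistical weight per conformer, the umbrella-refinement method
    optimizes a small per-observable force-constant vector k of a harmonic
    bias potential; the refined weights follow from the umbrella-sampling
    reweighting identity. Regularization strength is balanced by a
    hyper-parameter theta selected by k-fold cross-validation with a sigmoid
    validation score, and an ensemble-preservation diagnostic guards against
    overfitting collapse. Includes readers and writers for a plain-text
    two-file input convention, r^-6 preconditioning of NOE bounds, a
    synthetic dihedral-grid ensemble generator with Karplus-type observables
    for validation, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
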