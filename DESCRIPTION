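Package: smaopt
Title: Surrogate-Model-Assisted Optimization of Lennard-Jones Force-Field
    Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating the Lennard-Jones nonbonded parameters of a
    molecular force field against a bulk-phase density target and a set of
    relative conformational energies.  The package samples a four-dimensional
    (sigma_C, sigma_H, eps_C, eps_H) parameter space with grid and Sobol
    designs, evaluates candidate parameter sets through a configurable
    synthetic density oracle emulating the landscape of condensed-phase
    molecular-dynamics estimates, trains and benchmarks five families of
    regression surrogates (linear, polynomial, random forest, Gaussian
    process, feed-forward network) under an in-sample/out-of-sample testing
    protocol, and runs a box-constrained gradient-descent optimization in
    which the expensive density evaluation is replaced by the surrogate while
    a molecular-mechanics relative-conformational-energy objective is
    computed directly.  Optimized parameters are re-verified against the
    ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
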