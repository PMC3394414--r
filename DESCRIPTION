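Package: mdggm
Title: Generative Gaussian Graphical Models of Molecular Dynamics Trajectories
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns generative Gaussian graphical models (Gaussian Markov
    random fields) from molecular-dynamics covariate time series such as
    C-alpha positional fluctuations. Provides an L1-regularized precision
    matrix estimator solved by block coordinate descent on the dual
    maximum-determinant problem, kernel-smoothed time-varying models with
    sub-state segmentation diagnostics (entropy, predictive log-likelihood,
    sequential KL divergence), and Markov chains over KL-clustered window
    models that generate new synthetic trajectories and support perturbation
    inference by analytic Gaussian conditioning. Includes synthetic fixture
    generators with known ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, bio3d
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'model-core.R'
    'sparse-estimation.R'
    'time-varying.R'
    'kinetics.R'
    'covariates-io.R'
    'synthetic.R'
    'cli.R'
    'mdggm-package.R'
    'serialization.R'
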