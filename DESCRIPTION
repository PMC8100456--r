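Package: saxsbme
Title: Bayesian/Maximum Entropy Refinement of Disordered Protein Ensembles
    Against Small-Angle Scattering Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to refine heterogeneous conformational ensembles of
    intrinsically disordered proteins against experimental small-angle X-ray
    scattering (SAXS) profiles. Implements Bayesian/Maximum Entropy (BME)
    reweighting with a convex dual-space solver, coarse-grained Debye-equation
    SAXS forward models, Guinier analysis, an empirical radius-of-gyration to
    hydrodynamic-radius relation, paramagnetic relaxation enhancement (PRE)
    intensity-ratio back-calculation, L-curve selection of the regularization
    hyperparameter, block-averaged uncertainty estimation, a self-avoiding
    chain Monte Carlo generator for synthetic test ensembles with known ground
    truth, and a toy multi-replica metainference sampler with on-the-fly
    replica-averaged SAXS restraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
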