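Package: macroaxes
Title: Elaboration and Innovation Along Phylogenetic Major Axes of Trait Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates clade-nested evolutionary rate (R) matrices for
    multivariate traits on a phylogeny with a conjugate block-Gibbs sampler for
    the Bayesian phylogenetic mixed model, orchestrated as "mini-chains" over a
    distribution of trees with informed priors and a pre-estimated burn-in.
    Scores species and clades as elaborating along, or innovating away from,
    phylogenetic major axes of trait variation (projection/rejection geometry),
    and provides downstream axis-orthogonality summaries with posterior
    probabilities, Bhattacharyya overlap of score distributions, posterior
    elaboration-innovation correlations, Pagel's lambda, and a phylogenetic
    generalized least squares model suite. Includes a synthetic-data module
    generating trees, nested clade structures and traits under nested
    multivariate Brownian motion with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
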