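Package: maupbym
Title: Scale Effects of Areal Aggregation in Bayesian Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of areal aggregation level
    (the modifiable areal unit problem, MAUP) affects Bayesian disease
    mapping of sparse count data.  Provides nested areal hierarchies with
    queen or rook contiguity, population-weighted aggregation and
    disaggregation of counts and covariate scores through correspondence
    matrices, indirect age standardisation and standardised incidence
    ratios, a Metropolis-within-Gibbs sampler for the Besag-York-Mollie
    (BYM) Poisson model with an intrinsic conditional autoregressive
    structured effect and an independent unstructured effect, Moran's I
    permutation tests, Geweke convergence diagnostics, a synthetic-data
    generator emulating a five-level statistical geography, and an
    end-to-end experiment pipeline that compares inference across levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
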