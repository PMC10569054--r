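Package: cgnn
Title: Structure-Based Coarse-Grained Neural-Network Potentials by Inverse
    Monte Carlo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains Behler-Parrinello-style neural-network potentials for
    single-type coarse-grained particles so that Metropolis Monte Carlo
    sampling under the network reproduces reference radial distribution
    functions. The loss gradient with respect to the network weights is
    obtained from the inverse-Monte-Carlo fluctuation (covariance) formula
    rather than backpropagation through the sampler, and training can target
    several reference state points simultaneously to obtain transferable
    potentials. Includes a potential-of-mean-force pretraining stage, a
    self-contained Lennard-Jones reference generator, a classic tabulated
    inverse Monte Carlo baseline, and structural observables (radial
    distribution functions, triplet angle distributions, three-body energy
    decomposition maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
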