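Package: selfEstab
Title: Partial Selfing, Polygenic Load, and Establishment in a New Habitat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how partial self-fertilization shapes the genetic
    composition of a large source population and the probability that a handful of
    founders sampled from it establish a colony in a new habitat. Implements a
    deterministic selfing-age-cohort recursion (the ILEC approximation: identity and
    linkage equilibrium within cohorts) for polygenic mutation-selection balance with
    partially recessive deleterious alleles and codominant alleles under directional
    selection; an individual-based forward simulator of the partially selfing source
    population used to validate the approximation; and a founder-sampling plus
    hard-selection establishment simulator with a Poisson branching-process
    approximation for the establishment probability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'architecture.R'
    'fitness.R'
    'ilec-steps.R'
    'ilec-equilibrium.R'
    'ilec-summaries.R'
    'population.R'
    'establishment.R'
    'experiment.R'
    'selfEstab-package.R'
    'show-methods.R'
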