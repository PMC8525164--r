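Package: hostphylo
Title: Phylogenetic Analysis of Insect-Host Plant Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the evolution of host-plant use on insect
    phylogenies: host-breadth profiles and polyphagy partitions from curated
    association tables, phylogenetic signal tests (Blomberg's K with
    randomization, Pagel's lambda with likelihood-ratio test), a randomized
    source-host logistic regression of host sharing against host phylogenetic
    distance, strict-clock chronogram rescaling, and maximum-likelihood
    ancestral host-range reconstruction under the dispersal-extinction-
    cladogenesis model with the null range disallowed (DEC*). Includes
    forward simulators (Yule trees, Brownian and lambda-attenuated traits,
    distance-decay association systems, DEC* range histories) so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    Matrix,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
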