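Package: toxitrait
Title: Parsimony-Based Evolution of Mutually Exclusive Binary Toxin
    Traits over Posterior Tree Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of binary chemical traits
    (e.g. muscarine and psilocybin production in Inocybaceae mushrooms)
    on Bayesian posterior samples of dated phylogenies.  Codes
    heterogeneous literature assay reports into tip states with a
    simple-majority rule, geographic-proximity scoring and a
    mutual-exclusivity constraint; performs Fitch/Hartigan parsimony
    ancestral-state reconstruction with exact minimum/maximum gain and
    loss counts over every tree in a posterior sample; tests
    phylogenetic conservatism by tip-label randomization of the
    parsimony score; and tests monophyly of trait-positive taxa as a
    posterior proportion.  A fully seeded synthetic-data generator
    (Yule trees, Mk binary traits, a three-state mutually exclusive
    pair process, assay-report noise, missing-data masking and
    NNI-perturbed pseudo-posteriors) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
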