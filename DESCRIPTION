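Package: studsurv
Title: Offspring Survival over Generations of Captive Breeding from Studbook Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse offspring survival to reproductive maturity in
    managed (zoo and conservation) breeding programs from studbook pedigrees.
    Computes pedigree kinship, inbreeding coefficients, generations in
    captivity and Wright's effective population size; builds per-offspring
    analysis tables with survival labels, exclusion filters, litter
    identification, independent litter sampling and within-species
    standardization; fits binomial mixed models with nested random intercepts
    (species, birth program within species, year within species) and
    species-level random slopes; performs all-subsets AICc model selection
    with conditional model averaging and pooling across litter-sampling
    replicates; tests phylogenetic signal (Pagel's lambda) of species-level
    effects; and includes a forward studbook simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
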