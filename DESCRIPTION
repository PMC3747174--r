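Package: goCompare
Title: Global Comparison of Gene Lists Based on Functional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two lists of genes through their functional profiles,
    the vectors of annotation frequencies over a target set of Gene Ontology
    classes. Because GO classes overlap and the two lists may share genes,
    classical homogeneity tests are invalid for this comparison. The package
    implements a global test based on the squared Euclidean distance between
    profiles, whose null distribution is a mixture of chi-square variables
    derived from the multinomial covariance of the "expanded" profile over
    disjoint class combinations. It provides tail probabilities and quantiles
    for such mixtures, an asymptotic confidence interval for the profile
    distance, an approximate power calculator, class-by-class Fisher tests
    with Holm adjustment, a combined global/class-by-class decision
    procedure, readers for gene lists, annotation maps (TSV, GAF 2.x) and
    OBO ontologies with projection onto a fixed GO level, and a seeded
    simulation engine for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
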