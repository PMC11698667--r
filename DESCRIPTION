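Package: turnpike
Title: Reconstruction of One-Dimensional Point Sets from Unassigned Pairwise Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Solvers for the noisy Turnpike and Beltway problems: recovering n
    points on a line or circle from the unordered multiset of their pairwise
    distances, as arises in partial-digest restriction mapping. Implements a
    minorization-maximization scheme built on a sorting-based matching sweep,
    a divide-and-conquer refinement, block-descent solvers for partitioned and
    partially missing distance sets (labeled and simplified partial digests,
    circular instances), greedy/permutation/Gaussian initializers, and an
    exact mixed-integer formulation with lazy separation cuts for small
    instances. Includes synthetic-instance generators (distributional point
    sets with additive noise, simulated restriction digests, relative integer
    noise) and evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
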