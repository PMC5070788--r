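Package: seedforge
Title: Design of Multiple Spaced-Seed Pattern Sets by Hill Climbing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing sets of spaced seeds (binary match /
    don't-care patterns) for database searching, read mapping and
    alignment-free sequence comparison. Implements the overlap complexity
    of a pattern set, a closed-form approximation to the variance of the
    spaced-word match count between two sequences under an indel-free
    substitution model, an exact dynamic-programming computation of seed
    sensitivity in a Bernoulli homology model, and a contribution-sorted
    hill-climbing optimizer that minimizes overlap complexity or match-count
    variance, or maximizes sensitivity via the overlap-complexity surrogate.
    A Monte-Carlo simulator of sequence pairs validates the variance formula,
    and brute-force oracles validate the sensitivity computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
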