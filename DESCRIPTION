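Package: lotlang
Title: Bayesian Program Induction of Formal Languages over a Language of
    Thought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns generative programs for formal languages from positive
    string examples alone. Hypotheses are typed, possibly recursive, stochastic
    programs composed from a small inventory of domain-general primitives
    (list operations, Boolean logic, set sampling, and factor calls with
    optional stochastic memoisation). A probabilistic context-free grammar over
    expressions supplies a simplicity prior; a prefix likelihood with a
    delete-then-append noise channel scores data; posterior inference uses
    Metropolis-Hastings subtree-regeneration proposals inside an adaptive
    parallel-tempering scheme. Includes a registry of target formal languages
    across the Chomsky hierarchy and from artificial-language-learning
    paradigms, plus an evaluation harness computing posterior-weighted
    precision and recall learning curves against a memorisation baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
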