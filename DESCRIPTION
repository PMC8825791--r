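Package: altgame
Title: Memory-One Strategies and Cooperation in Alternating Donation Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for direct reciprocity when players take turns rather than
    moving simultaneously. Computes exact long-run payoffs for pairs of
    memory-one strategies in the alternating and simultaneous donation game
    (with implementation errors, discounting, and irregular alternation),
    characterizes the Nash equilibria among memory-one strategies (partner,
    defector, and equalizer strategies, with and without errors) via
    closed-form conditions and a four-deviation verification recipe, and
    simulates pairwise-comparison evolutionary dynamics in well-mixed
    populations (including the rare-mutation limit with analytic fixation
    probabilities) as well as imitate-the-best dynamics on a periodic lattice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
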