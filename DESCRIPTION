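Package: ugevolve
Title: Evolution of Conditional Ultimatum Game Strategies with Kin Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of the one-shot anonymous
    Ultimatum Game in which strategies carry a heritable kin tag and
    recognition threshold and may play different (offer, demand) branches
    against partners classified as kin or non-kin. Provides Wright-Fisher
    evolution with tunable selection strength, line-of-descent reconstruction
    and summaries, selection-strength sweeps with replicate management, an
    evolutionary-stability predicate, and an inference toolkit that turns
    empirical acceptance-rate tables into a single (offer, demand) strategy
    vector via a logistic acceptance fit, an offer-independent demand
    threshold, and a payoff-maximising offer. All user-facing functions take
    and return tibbles; results have tidy() and glance() methods and ggplot2
    plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
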