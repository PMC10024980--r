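Package: segsolve
Title: Stackelberg Evolutionary Games: Eco-Evolutionary Equilibria and
    Leader Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Stackelberg evolutionary games between a rational
    leader (a manager, physician or harvester) and evolving followers whose
    eco-evolutionary dynamics derive from a fitness-generating (G-) function.
    Provides Darwinian dynamics (coupled population and trait ODEs),
    ecological equilibria, evolutionarily stable strategy (ESS) computation
    with invasion and convergence-stability tests, ESS branch continuation
    with pitchfork bifurcation detection, and the leader's naive, Nash
    (ecologically enlightened) and Stackelberg (evolutionarily enlightened)
    strategies with first-order-condition diagnostics.  Includes two worked
    models: a fisheries harvest game with an evolving catchability trait and
    an adaptive cancer-therapy game with sensitive and resistant cell types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
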