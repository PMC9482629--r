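Package: soyshift
Title: Counterfactual Analysis of Deforestation Leakage from Zero-Deforestation Soy Supply-Chain Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale applied general-equilibrium (AGE) pipeline for
    quantifying how much of the deforestation avoided by zero-deforestation
    supply-chain policies in the Brazilian soy sector is displaced ("leaks")
    to unrestricted regions at home and abroad. Includes a synthetic
    mini-world generator (balanced social accounting matrix, municipality
    land-cover layer, trader export tables), policy-footprint construction
    from committed-trader market shares, a multi-region equilibrium model
    with nested constant-elasticity-of-transformation land supply and an
    endogenous-subsidy land-conversion freeze, leakage-rate decomposition,
    land-use-change greenhouse-gas accounting, a scenario grid and a
    systematic sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
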