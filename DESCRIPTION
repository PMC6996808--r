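Package: lencomm
Title: Length-Structured Multispecies Fish Community Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A deterministic length-structured model of an interacting fish
    community. Species dynamics are resolved on a shared grid of discrete
    length classes and advanced in sub-annual time steps through three
    phases: recruitment (five stock-recruitment families), mortality
    (background, size-preference predation, and multi-gear fishing), and
    von Bertalanffy growth between classes. A fisheries layer supports
    multiple gears with logistic, log-Gaussian or knife-edge catchability
    and dynamic yearly effort. Analysis tools compute community indicators
    (biomass, spawning stock biomass, large fish indicator, mean maximum
    length, typical length, length quantiles, catch per unit effort),
    single-species FMSY, multispecies Nash equilibria by best-response
    iteration, and mixed-fishery scenario grids with a collapse criterion.
    A synthetic North-Sea-like parameter generator provides reproducible
    test communities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
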