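Package: ohpgame
Title: Tripartite Evolutionary Game Dynamics of Online Healthcare Platform Adoption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models the promotion of an online healthcare platform (OHP) as a
    three-population evolutionary game between doctors (join / not join),
    patients (use / not use) and platforms (provide / not provide standardized
    services). Builds the 2x2x2 payoff tensor from 23 model parameters,
    derives replicator dynamics on the unit cube, integrates strategy-share
    trajectories, enumerates and classifies fixed points (corner and interior)
    by Jacobian eigenvalue analysis, and ships a library of parameter-sweep
    scenarios covering qualification-inspection strength, information-protection
    investment, initial adoption shares, and cost levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
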