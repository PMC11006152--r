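Package: chemocoop
Title: Chemostat Models of Public-Goods Cooperation and Social Cheating
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic chemostat models of cooperative extracellular
    protease production and social cheating in Pseudomonas aeruginosa.
    Implements a five-state substrate/product/enzyme/cooperator/cheater
    ODE system with a Hill-type quorum-sensing burden, Monod growth and
    Michaelis-Menten proteolysis, batch-then-chemostat culture protocols,
    six-state variants for evolved faster-growing mutants, derived
    observables (optical density, cheater frequency, fitness, saturation
    limits), an ensemble random-sampling calibration pipeline with
    success filtering and weighted normalized RMSE scoring, one- and
    two-parameter sensitivity scans, and a synthetic-data generator that
    emulates chemostat time-series measurements with plate-count noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
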