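Package: critdom
Title: Critical Domain Size for Populations Subject to Demographic and
    Environmental Stochasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic analogues of linear integrodifference equations for
    populations with distinct dispersal and reproduction stages. Provides a
    spatially explicit individual-based simulator, a population-level
    approximation built on the Central Limit Theorem, a dispersal-modified
    Galton-Watson branching process, and a branching process in iid random
    environments. Computes dispersal-success approximations for symmetric
    kernels, finite-horizon and ultimate extinction probabilities,
    criticality conditions, and critical domain sizes, including inverse
    solvers for conservation goals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
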