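Package: oscimmune
Title: Oscillatory Collateral-Damage Models of Autoimmune Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a theoretical model of autoimmune response in which a
    trigger (virus, bacterium or toxin) partitions host cells into two altered
    populations whose interaction is mediated by three signals. Implements the
    linearized three-signal dynamics with their oscillation conditions,
    closed-form health and collateral-damage curves versus trigger dose, a
    sigmoid second-messenger trigger-pathway cascade, a buffered
    reaction-diffusion trigger model with rapid-equilibrium reduction, and a
    pairwise sign-pattern screen for identifying signal pairs capable of
    sustaining autoimmune oscillations. Every closed form is paired with an
    independent numerical oracle (ODE integration or adaptive quadrature).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
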