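Package: nmrbind
Title: Self-Association, DNA Binding and Degradation Kinetics from NMR
    Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic and kinetic inference from solution NMR
    observables for small aromatic drugs that stack with themselves and
    with short DNA duplexes.  Fits the isodesmic (indefinite, equal-K)
    self-association model to dilution chemical-shift series, 1:1
    host-guest binding constants to chemical-shift titrations against a
    DNA duplex, closed-form binding constants to fast-exchange-averaged
    diffusion (DOSY) measurements, and first-order degradation kinetics
    with half-life estimation.  Ships seeded synthetic-data generators
    for every experiment type so each fitting routine is verifiable by
    parameter recovery, plus validated CSV readers/writers, broom-style
    tidiers, ggplot2 plotting, and an end-to-end study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
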