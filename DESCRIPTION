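Package: motrack
Title: Index-Free Multiple Object Tracking Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates classic multiple object tracking (MOT) displays and an
    index-free tracking observer. Object motion follows constant-speed dynamics
    with inverse-square repulsion, Ornstein-Uhlenbeck dynamics (optionally with
    a minimum-separation constraint), or shell-game arc dynamics designed to
    scramble the spatial order of well-separated objects. The observer maintains
    a retinotopic map of attended locations updated one location per tick by a
    bounded nearest-object search, augmented by a single capacity-two unitary
    buffer that extrapolates the velocity of the most confusable target, and an
    explicitly maintained spatially sorted label sequence for identity
    reporting. Includes experiment presets, unit conversions between empirical
    and simulated object speeds, an adaptive staircase, speed-threshold search,
    grid-search parameter fitting, plain-text trajectory files and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
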