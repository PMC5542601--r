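Package: seinesim
Title: Coupled Rope-Dynamics and Fish-Herding Simulation of Demersal Seine Fishing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain simulation of demersal (Danish/Scottish) seine fishing.
    A lumped-mass model of two long seine ropes dragged and winched across a flat
    seabed produces gear kinematics, which drive an agent-based model of cod
    reacting to the approaching ropes. The package constructs idealized rope
    layout patterns (rectangle, square, triangle, diamond), simulates haul-in
    procedures with and without a towing phase, and logs catch-performance
    indicators: the area encircled by the seabed-contacting rope sections, the
    entry width between the ropes, and the number of fish encircled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
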