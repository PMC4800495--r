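Package: stomawave
Title: Stomatal Conductance Schemes and Heatwave Diagnostics for a
    Single-Column Land Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to explore how the representation of stomatal
    conductance propagates into simulated evapotranspiration and
    temperature extremes. Implements a Farquhar-type C3 leaf
    photosynthesis model with peaked temperature responses, two coupled
    stomatal conductance schemes (the optimal-theory model with
    per-plant-functional-type g1 and a Leuning-type empirical model with
    pathway-level parameters), estimation of g1 from leaf gas-exchange
    data, a daily big-leaf bucket land-surface column driven by a
    stochastic weather generator with atmospheric-blocking episodes,
    calendar-day percentile heatwave indices (duration, frequency,
    intensity, maximum intensity, TXx), and paired control/experiment
    ensemble analysis with Student's t-tests and false-discovery-rate
    field significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
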