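Package: selrisk
Title: Agent-Based Simulation of Cumulative Sound Exposure Risk for
    Marine Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the risk that intense anthropogenic
    underwater sound (sonar, pile driving, seismic surveys) poses to
    marine mammals.  Thousands of animal agents are seeded from a gridded
    density surface and moved through a duty-cycled sound field with a
    directed random walk (wrapped-normal headings, optional aversion to
    the source, reflecting boundaries and land/seafloor constraints).
    Received levels from a geometric-spreading propagation model are
    frequency-weighted by functional-hearing-group (M) or
    audiogram-derived (A) weighting functions and accumulated into
    per-agent cumulative sound exposure levels (SEL).  Risk summaries
    report the fraction of animals exceeding permanent/temporary
    threshold-shift (PTS/TTS) criteria, expected counts under a logistic
    dose-response curve, gridded risk maps, and Monte-Carlo confidence
    intervals that propagate density uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
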