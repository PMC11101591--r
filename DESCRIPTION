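Package: bmusim
Title: Discrete Spatio-Temporal Simulation of Trabecular Bone Remodelling
    and Mineralisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete statistical simulator of trabecular bone remodelling
    on a 2D pixel lattice. Individual basic multicellular units (BMUs) are
    activated on bone surfaces by targeted remodelling, resorb hemiosteonal
    (semi-circular) cavities, and refill them after a quiescent reversal
    phase, with optional underfilling. Newly formed osteoid mineralises
    under a calibrated double-exponential law (fast primary phase to ash
    fraction 0.45, slow secondary phase towards the ~30 wt% calcium cap).
    The package computes bone mineral density distributions (BMDD) and
    their descriptors (Ca_MEAN, Ca_PEAK, Ca_WIDTH, skewness), apparent
    density and area-fraction time series, parameter sweeps over activation
    frequency and secondary mineralisation time, and preset osteoporosis
    scenarios (high formation period, high activation frequency,
    underfilling, no filling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
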