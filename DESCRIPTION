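Package: candykano
Title: Interval Kano ('Candy') Model for Survey-Based Requirement Classification
Version: 1.0.0
Authors@R:
    person("Service", "Analytics", email = "svc-analytics@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying service requirements from bipolar
    (forward/reverse) five-point Kano questionnaires. Implements the
    interval-threshold ratio classifier ('Candy' model), which normalizes
    per-item satisfaction and dissatisfaction scores into relative shares
    and partitions items into Critical, Must-be, One-dimensional,
    Attractive and Indifferent categories using a floating interval around
    the grand mean, alongside the traditional evaluation-table (frequency)
    method, Better-Worse satisfaction coefficients, and the simple
    ratio-quadrant model. Includes questionnaire I/O and validity
    filtering, reliability and validity statistics (Cronbach's alpha, KMO,
    Bartlett's sphericity), importance and correlation analysis,
    stratified subgroup comparison with requirement life-cycle chain
    distances, a seedable synthetic questionnaire generator, and a
    command-line pipeline. Ships a 46-item home-based elderly-care
    service catalog and profile tables as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
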