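Package: resinopt
Title: Optimization-Based Resin Selection and Elution Pooling for
    Multi-Step Protein Chromatography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decision support for downstream purification process
    development. Reads high-throughput microscale chromatography
    screening data (loaded and collected protein mass per resin,
    operating condition and elution time interval), predicts the
    performance of integrated multi-step separations under a constant
    load-collection-ratio mass balance, and selects resins, operating
    conditions and elution collection cut-points that maximize
    target-protein yield and purity.  The yield-purity trade-off is
    mapped as a Pareto frontier with the epsilon-constraint method;
    each fixed-purity subproblem is a mixed-integer linear fractional
    program solved by Dinkelbach's algorithm over a sequence of
    mixed-integer linear programs.  Ships a seeded synthetic-data
    generator emulating two-step cation-exchange / mixed-mode screens
    and an exhaustive-enumeration oracle for verification on small
    instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9)
    available as 'python' on the PATH (used for mixed-integer linear
    programming via the HiGHS solver in scipy.optimize.milp)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
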