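Package: peatthaw
Title: Northern Peatland Carbon and Nitrogen Stocks and Permafrost Thaw
    Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A data-driven inventory and projection framework for northern
    peatland carbon and nitrogen. Generates synthetic peatland landscapes
    and peat-core samples with realistic depth, bulk-density and
    organic-carbon distributions; fits linear depth-to-storage models and
    aggregates area-weighted C and N stocks; models equilibrium permafrost
    fraction in peatlands as a complementary-error-function curve of mean
    annual air temperature and projects permafrost peatland extent under
    warming stabilization scenarios; assembles baseline greenhouse-gas
    budgets from a logistic carbon-accumulation model and stage-specific
    flux tables; runs four-stage permafrost-thaw transition scenarios with
    a chronosequence-based carbon-loss equation and C:N scaling; and
    converts flux series into radiative-forcing trajectories with an
    impulse-response engine for CO2, CH4 and N2O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
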