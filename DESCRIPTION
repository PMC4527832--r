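Package: coldstreams
Title: Coldwater Stream Habitat Vulnerability to Warming and Acidification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage assessment of coldwater stream habitat vulnerability
    over dendritic river networks. Generates seeded synthetic watersheds with
    realistic topology, landscape covariates, acid neutralizing capacity (ANC)
    fields, and daily air/water temperature series; fits a multiple linear
    regression for July mean daily maximum stream temperature (JMMST) with
    exhaustive AIC subset selection under a per-term significance constraint;
    estimates per-site air-water thermal sensitivity slopes and models them
    with a logistic high/low gate plus a continuous slope regression; performs
    two-step ANC estimation (binomial 300 ueq/L gate, linear model for low-ANC
    reaches) with monotone bias recalibration; and accounts suitable habitat
    length under dual temperature/ANC thresholds across climate warming
    scenarios, by management unit.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
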