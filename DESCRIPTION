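Package: wardopt
Title: Stochastic Ward Capacity Modelling and Cost-Based Patient Admission Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decision support for hospital bed management with shared ward
    resources. Length of stay is modelled as a log-normal random variable
    elicited from an expected discharge date and an uncertainty interval;
    expected ward occupancy is the mean of a Poisson-binomial sum of the
    occupants' survival probabilities. Elective admission requests are
    scheduled by minimising a four-factor assignment cost (clinic-ward
    affinity, ward occupancy, occupancy change, admission delay) either
    exactly, through a binary integer program solved by a pluggable MILP
    backend, or by greedy list-scheduling heuristics (LEPT, SEPT, random
    order) and a status-quo baseline. A discrete-event simulation of a
    synthetic hospital evaluates the strategies on paired random streams
    and summarises dismissal ratios, cost decompositions and runtimes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
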