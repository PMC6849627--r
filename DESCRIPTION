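Package: peatsim
Title: Cohort-Based Peatland Carbon and Water-Table Simulation with
    Palaeohydrological Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annual-timestep cohort model of blanket-bog peat
    accumulation driven by temperature and precipitation: water-table
    dynamics through an exponential air-filled pore-space function with
    bedrock drainage, plant-functional-type composition from five-year
    water-table averages, oxic/anoxic litter decomposition with CO2/CH4
    partitioning and methane oxidation, and grouse-moor management
    scenarios (rotational burning with sigmoidal net-primary-production
    recovery and charcoal input, and grip drainage with a dated
    efficiency schedule).  Alongside the simulator the package provides
    a weighted-averaging tolerance-downweighted transfer function with
    inverse deshrinking and bootstrap sample-specific errors for
    reconstructing water-table depth from testate-amoeba assemblages, a
    spheroidal-carbonaceous-particle age-depth model, regression-based
    offset correction for proxy-model comparison, and synthetic-data
    generators (climate, training sets, fossil cores, SCP profiles) so
    the whole pipeline is testable without external data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    yaml
Config/testthat/edition: 3
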