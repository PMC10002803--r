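Package: equiscreen
Title: Catchment and Location-Allocation Analysis of Mammography Screening Access
Version: 0.1.0
Authors@R:
    person("Equiscreen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing geographic access to screening mammography:
    guideline-based screening demand estimation (USPSTF, race-based, ACR),
    facility capacity modelling, road-network drive-time catchments at 15/30
    minute bands, Poisson rate regressions of facility counts on tract
    covariates with a population offset, and capacitated maximal-covering
    siting of new facilities via greedy construction with pairwise
    interchange. Ships a seeded synthetic-geography generator emulating a
    small US state (one urban and several rural counties) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
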