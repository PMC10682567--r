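Package: lobexsert
Title: Geographic Analysis of Stylar Exsertion in Lobelia Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing latitudinal and range-marginal variation in
    stylar exsertion (outcrossing capability) of North American Lobelia from
    photo-scored community-science occurrence records. Provides record
    parsing, validation and a reproducible filter cascade with audit reports;
    a proportional range-marginality index built from great-circle distances
    to the species range center and to the convex hull of all occurrence
    coordinates; covariate construction with global and species-centered
    z-score standardization; binomial and Poisson generalized linear models
    fit by iteratively reweighted least squares with Wald inference,
    inverse-link prediction surfaces, estimated marginal means and
    multiplicity-adjusted pairwise species contrasts; and a synthetic
    occurrence-record generator with known hurdle-model parameters so every
    pipeline stage can be verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    lubridate,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    emmeans,
    geosphere,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
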