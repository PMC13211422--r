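Package: soilsrc
Title: Soil Heavy-Metal Pollution Indices and Receptor-Model Source Apportionment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of heavy-metal contamination in agricultural soils:
    enrichment factor, geoaccumulation index, single-factor and Nemerow
    integrated pollution indices, and the Hakanson potential ecological risk
    index with their standard grade scales; source apportionment by absolute
    principal component score multiple linear regression (APCS-MLR) and by
    positive matrix factorization (PMF) with measurement-uncertainty
    weighting, factor-number scans and bootstrap factor mapping; per-metal
    random-forest screening of environmental covariates with permutation
    importance; and a ground-truthed synthetic geochemical mixture generator
    so the whole pipeline is testable without survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
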