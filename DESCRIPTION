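Package: onionfly
Title: Phenology of Summer-Diapause Termination and Adult Emergence in
    the Onion Maggot
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasting toolkit for late-season adult emergence of the
    onion maggot (Delia antiqua) from summer-diapausing pupae. Provides
    Lactin temperature-dependent rate curves and Weibull development-time
    distributions with deterministic least-squares fitting, a two-phase
    daily cohort simulation (summer-diapause termination followed by
    post-diapause pupal development) driven by daily weather series,
    air-to-soil temperature conversion, degree-day generation tracking
    with a common base temperature, a synthetic-weather generator for
    regional summer profiles, and observed-versus-predicted evaluation
    of emergence percentile dates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
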