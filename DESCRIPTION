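Package: spotsodium
Title: Estimating 24-Hour Urinary Sodium Excretion from Spot Urine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population sodium-intake surveillance when complete
    24-hour urine collection is impractical. Simulates adult cohorts with
    realistic anthropometry and urine biochemistry, screens 24-hour
    collections for completeness, develops spot-urine prediction equations
    for 24-hour sodium excretion by stepwise multiple linear regression
    with double cross-validation and shrinkage diagnostics, and validates
    predictions against measured sodium and against the Tanaka and
    INTERSALT equations using Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    readr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
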