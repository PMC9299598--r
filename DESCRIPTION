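Package: recredit
Title: Crediting Error Analysis for Improved Forest Management Carbon Offsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replicates upfront credit issuance for improved forest management
    (IFM) carbon offset projects, re-estimates regional "common practice" carbon
    stocks at species/forest-type resolution from forest-inventory condition
    records instead of coarse assessment-area averages, recomputes credits under
    the species-specific baselines, and propagates inventory sampling
    uncertainty by Monte Carlo into per-project and program-wide crediting-error
    distributions. Includes a synthetic-data generator that emulates the
    statistical structure of national forest inventory condition tables and
    digitized offset-project records, with closed-form ground truth for
    parameter-recovery testing, and a radius-neighbors classifier that maps
    reported species compositions to forest-type codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
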