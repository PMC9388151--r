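Package: foodprint
Title: Environmental Impact and Nutrition Scoring of Multi-Ingredient Food
    Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-100 g environmental impacts (greenhouse gas
    emissions, land use, scarcity-weighted water use, eutrophication
    potential) and nutrition quality (NutriScore) of multi-ingredient
    retail food products from back-of-pack ingredient lists.  Infers the
    percent-by-mass of each ingredient from its list position, declared
    QUID percentages and priors built from similar products, propagates
    production-system uncertainty through a Monte Carlo analysis over an
    environmental intensity database, condenses the four indicators into
    a composite 0-100 impact index, and provides a masking-based
    validation harness that compares estimated against known impact
    scores.  Includes a synthetic corpus generator so the full pipeline
    can be exercised without licensed retailer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
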