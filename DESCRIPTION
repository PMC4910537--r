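Package: dietpatterns
Title: Dietary Pattern Identification from Food-Consumption Surveys via
    Weighted Non-Negative Matrix Factorisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies latent consumption systems in sparse, non-negative,
    survey-weighted food-consumption data using a weighted least-squares
    non-negative matrix factorisation (LS-NMF) with multiplicative updates,
    clusters individuals into dietary patterns by mass-weighted Ward
    hierarchical clustering with inertia-ratio based cluster-count selection,
    and characterises each pattern by V-tests, relative consumption-system
    contributions, nutrient intakes, diet-quality indices (mean adequacy
    ratio, energy density, dietary diversity score), contaminant exposure per
    kg body weight, a correspondence-analysis wealth index and sex-stratified
    logistic determinants. A synthetic-data generator emulates a national
    7-day food-record survey so the whole pipeline is testable without
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
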