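Package: sustdiet
Title: Optimization of Nutritionally Adequate, Low-Emission and Culturally
    Acceptable Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves the two classic diet-optimization programs used
    to study the cost and climate impact of sustainable diets: a minimum-cost
    linear program and a minimum-deviation quadratic program that minimizes the
    sum of squared relative deviations from the observed diet. Both operate on
    a food universe of (by default) 74 food categories mapped to 16 main
    categories, subject to an isocaloric energy equality, nutrient adequacy
    bounds, a greenhouse-gas emission cap, a dairy-beef jointness constraint
    reflecting that dairy production co-produces beef, and food-habit box
    bounds at the 10th and 90th centiles of observed consumption. Includes the
    survey-side data preparation arithmetic (unit-value prices, consumption-
    share nutrient aggregation, OECD-equivalized income strata, habit
    percentiles), an exact additive intra-/inter-category decomposition of
    changes in diet cost and emissions, scenario reporting with category
    shares, and a seeded synthetic-data generator that emulates the
    statistical structure of Finnish dietary survey data so that the whole
    pipeline is testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
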