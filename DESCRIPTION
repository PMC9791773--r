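Package: cpdi
Title: Chinese Preschooler Dietary Index Scoring and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Chinese Preschooler Dietary Index (CPDI), an
    age-stratified, energy-density-based diet-quality score (0-90 points,
    11 components) for children aged 2-5 years, from multi-day 24-h
    dietary recall records. Provides the published scoring standard as
    editable data, piecewise-linear adequacy/moderation/limitation
    component scoring on per-1000-kcal densities, plausible-energy
    record filtering, diet-quality categorization by cohort percentiles,
    nutrient adequacy ratios, internal-consistency reliability
    (Cronbach's alpha, item-rest Spearman correlations) and principal
    component dimensionality of the index, a synthetic-cohort generator
    with known ground truth for testing, CSV input/output, a toy
    food-composition conversion path, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
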