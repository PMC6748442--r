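Package: normsim
Title: Simulation and Evaluation of Continuous Test-Norming Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well continuous norming procedures recover
    age-specific norm scores for psychometric tests. Provides a developmental
    population model with Rasch-simulated raw scores on item scales of varying
    difficulty, a semi-parametric norming engine (polynomial regression of raw
    scores on rank-based person location and age, with best-subset term
    selection and monotonicity repair), parametric baselines (normal-family
    norming via age polynomials of mean and standard deviation, and Box-Cox
    Cole-Green norming fitted by joint maximum likelihood), and a Monte-Carlo
    harness that cross-validates every method against ideal norms from a large
    perfectly representative sample, reporting RMSE, mean signed difference,
    ability-band error profiles, win counts and inclusion rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
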