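Package: flyoperant
Title: Closed-Loop Operant Heat-Conditioning Analysis for Drosophila Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop operant conditioning experiments in which a
    fruit fly's own walking triggers a mild heat stimulus while a yoked partner
    receives the identical stimulus train and a blank partner receives none.
    Provides a semi-Markov fly simulator with a virtual stimulus controller and
    the full five-session protocol (Pre-test, two Train sessions with
    movement-triggered heat, two Test sessions), CSV trace input/output,
    walk/pause bout segmentation, the behavioural metrics used in this design
    (activity level, cumulative active duration, state-conditional heat
    likelihood, exposure differential, activity difference), curation rules,
    and a rank-based inference layer (Kruskal-Wallis, pairwise Wilcoxon with
    Holm adjustment, bootstrap median confidence intervals, permutation tests,
    correlation with slope). A pipeline function runs simulation or user data
    end to end and returns tidy tables and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
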