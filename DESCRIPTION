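Package: clicktrails
Title: Markov Chain Analysis of Mobile App Clickstream Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw mobile-app click logs into interpretable usage models.
    Provides inactivity-gap sessionization, first-order Markov chain
    estimation with a surrogate absorbing exit state, sequence-likelihood
    scoring, hard-EM clustering of session trails into a mixture of Markov
    chains, session simulation, a ground-truth-labelled synthetic log
    generator emulating a small mHealth field trial, and export of
    threshold-filtered navigation graphs for browser-based visualization.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
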