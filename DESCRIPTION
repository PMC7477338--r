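Package: tfnorm
Title: Temporal-Frequency and Contrast Tuning Analysis with Divisive
    Normalization Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how temporal-frequency tuning and contrast
    response interact in visual cortex recordings made with drifting
    gratings.  Extracts evoked firing rates from trial-level spike times,
    fits difference-of-Gaussians temporal-frequency tuning curves and
    Naka-Rushton contrast-response functions per unit, derives tuning
    characteristics (optimal frequency, half-maximum frequencies,
    band/low-pass class, C50, dynamic range), and fits the divisive
    normalization population model in static, shunting and linear variants.
    Includes a synthetic spiking-population generator with retained ground
    truth for parameter-recovery testing, a dLGN population-tuning proxy
    built from literature summary characteristics, and the nonparametric
    statistical battery used for cohort comparisons.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
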