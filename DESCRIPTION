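Package: combogate
Title: Combinatorial Expansion of Nested Flow Cytometry Gating Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Expands a minimal set of nested quadrant-gating frequencies
    (percent-of-parent values exported from cytometry analysis software)
    into the frequencies of every cell population definable by taking each
    of M panel markers as positive, negative, or not considered: 3^M - 1
    populations in all. Reads the two common CSV dialects (decimal point
    with comma separators, decimal comma with semicolon separators),
    writes the full samples-by-populations matrix, and provides the
    downstream analyses typically applied to it: per-population
    autoscaling, principal component analysis, and hierarchical
    clustering with a Pearson-correlation distance. A synthetic
    single-cell event simulator doubles as a brute-force counting oracle
    that verifies every computed population frequency against direct
    event counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
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
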