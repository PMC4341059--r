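Package: fluorosim
Title: Monte Carlo Simulation of Single-Molecule Peptide Fluorosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-molecule peptide sequencing by Edman degradation
    ("fluorosequencing"): in-silico proteolytic digestion of a proteome,
    anchor-based peptide retention, selective fluorescent labeling of amino
    acid types, and cycle-by-cycle observation of luminosity drops. Implements
    the three dominant experimental error processes (dye failure, Edman cycle
    inefficiency with negative-binomial interval dilation, and exponential
    photobleaching), collates simulated reads into a prefix-trie-equivalent
    attribution table with per-source-protein counts, and derives attribution
    probability mass functions, unique attributions, and proteome coverage
    under ideal and error-laden conditions. Includes a synthetic-proteome
    generator, deterministic ideal-coverage curves, and a reproducible
    parameter-sweep driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
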