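Package: hosnmr
Title: Higher-Order Structure Comparability of Biologics by 2D Methyl NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical comparability analysis of two-dimensional 1H-13C
    methyl NMR fingerprints of protein therapeutics. Computes combined
    chemical shift differences (CCSD) between matched cross-peaks of peak
    lists, average CCSD with confidence intervals and pairwise CCSD
    matrices, detects disappeared spin systems, bins gridded spectra on a
    fixed chemical-shift grid with total-area normalization, and compares
    binned spectra by principal component analysis and Euclidean
    distances. Includes a synthetic 2D-spectrum generator with known
    ground truth (batch, time-point and stress-treatment designs) so
    every stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
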