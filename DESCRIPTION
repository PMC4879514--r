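Package: exprdiverge
Title: Expression Divergence Between Closely Related Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene expression divergence between two
    closely related species from multi-organ RNA-seq FPKM data. Implements
    density-peak zFPKM normalization with expressed-gene calling, expression
    P_ST (a Q_ST analogue on expression traits) with variance-component
    estimation, individual-level permutation nulls and resampling-corrected
    p-values, the organ-specificity index tau, correlate analyses of
    divergence against pleiotropy proxies and sequence evolution, NMDS
    ordination of samples, detection of species-unique expressed genes, and a
    coverage-based screen for fixed genomic deletions. A synthetic-data
    generator emulating a two-species, multi-organ population sampling design
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    cluster,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
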