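Package: copymix
Title: Haplotype-Based Ancestry Estimation from Chromosome-Painting Copying Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a recipient individual's chromosome-painting copying
    vector (the per-donor-cluster genome length, in cM, copied under a
    CHROMOPAINTER-style model) into mixture proportions over surrogate
    reference clusters. Implements the SOURCEFIND Bayesian
    Dirichlet-multinomial model with Metropolis-Hastings sampling of the
    mixture coefficients and their concentration hyperparameters, a
    non-negative least-squares baseline, a synthetic-panel simulator for
    parameter-recovery experiments, post-processing of dated admixture-event
    tables (event simplification, date filters, calendar conversion,
    one-sided rank-sum comparison of date distributions), and a
    local-ancestry-conditioned allele-frequency differentiation test with
    FDR control and a matched-SNP resampling null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    pracma,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
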