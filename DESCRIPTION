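Package: genegate
Title: Gene Selection with a Non-Negative Gating Layer and Rank-Tally Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embedded feature selection for gene expression matrices using a
    multiplicative gating layer trained jointly with a dense neural-network
    classifier. Gate weights are constrained to be non-negative; gene
    importance is the number of training trials, over many independent random
    seeds, in which a gene's gate weight ranks among the N largest. Includes
    per-gene min-max normalization, a synthetic-data generator with planted
    class-informative genes, and Kaplan-Meier best-cutpoint survival
    validation via an exhaustive log-rank scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
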