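Package: pepperdiv
Title: Genetic and Phenotypic Diversity Analysis of Pepper Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diversity analysis of codominant marker (SSR/InDel) and
    phenotype data for germplasm panels, as applied to Chinese pepper
    landraces (LLR) and current breeding lines (CBL). Implements Shannon
    phenotypic diversity indices with the 1-10 quantitative scoring scheme,
    per-locus diversity statistics (gene diversity, observed heterozygosity,
    polymorphism information content), Cavalli-Sforza and Edwards chord
    distances with neighbour-joining and UPGMA trees, a Bayesian
    admixture-model Gibbs sampler with Evanno delta-K model choice,
    principal coordinate analysis, and a Balding-Nichols synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
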