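Package: wtfdrive
Title: Competing Gamete-Killing Meiotic Drivers and the Fitness Landscape of Fission Yeast Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and population genetics of competing wtf
    poison-antidote gamete killers in Schizosaccharomyces pombe. Provides exact
    enumeration and Monte-Carlo sampling of single meioses with chromosome-3
    missegregation, recombination, unequal crossovers and poison/antidote spore
    survival; a deterministic recursion for the invasion of chromosome
    segregation-infidelity mutants in a population segregating n drivers,
    including the cost-free critical drive strength n/(2(n-1)); the genetic
    assay statistics used on spore count and fertility tables (disomy frequency,
    allele transmission, G-tests, Wilcoxon tests, viable spore yield, map
    distance, power analysis); and a synthetic source-data generator with
    drive-strength parameter recovery.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
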