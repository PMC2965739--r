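Package: geneforce
Title: Phenotype-Driven Refinement of Integrated Metabolic and Regulatory Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconciling integrated constraint-based metabolic and
    Boolean transcriptional-regulatory models with observed growth phenotypes.
    Implements flux balance analysis (FBA) and steady-state regulatory FBA
    (SR-FBA) as linear and mixed-integer programs, and a rule-violation
    minimization algorithm that finds the smallest set of regulatory rules
    which must be overridden (genes forced to an expressed state) for the
    integrated model to reach a threshold growth rate. Supports enumeration of
    alternative optimal violation sets via integer cuts, three-way
    experiment/metabolic/integrated phenotype comparison grids, Biolog-style
    growth calling, cross-organism regulatory rule transfer through ortholog
    maps, and generation of synthetic planted-error models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    xml2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
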