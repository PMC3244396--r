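Package: lcgwas
Title: Latent-Class Subtyping of Psychiatric Comorbidity and Genome-Wide
    Association with Class Membership
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits binary-indicator latent class models by multi-start EM to
    uncover comorbidity subtypes in psychiatric case samples, selects the
    number of classes by BIC, and tests genome-wide SNP panels for
    association with latent-class membership probability under dominant,
    additive and recessive genetic models. Includes EIGENSTRAT-style
    principal-component stratification correction, Bonferroni and
    permutation multiplicity control, per-genotype phenotype summaries, and
    a synthetic cohort generator with planted class-specific genetic
    effects so every stage of the pipeline is testable without
    access-controlled genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
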