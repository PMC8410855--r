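Package: modflex
Title: Modular Pharmacology of Multi-Target Drugs from Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis for modular
    pharmacology of multi-target drugs in two-arm, two-timepoint
    transcriptomic studies. Detects co-expression modules with eigengenes,
    calls differentially expressed modules by permutation-based composite
    Z-summary preservation statistics, reconstructs the module-level network
    from connectivity scores with small-world topology metrics, stratifies
    treated subjects by clinical response to select the most effective
    therapeutic module, and quantifies modular flexibility across response
    strata with a Euclidean topological distance regressed on response. A
    seeded synthetic-study generator with planted modules, treatment-induced
    module dissolution, and a phenotype coupled to a causal module's
    eigengene change makes the whole pipeline testable without patient data.
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
    igraph,
    jsonlite,
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
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
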