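Package: bic2pam
Title: Constraint-Guided Pattern-Based Biclustering of Expression Data and Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern-based biclustering of real-valued gene-expression matrices and
    weighted biological networks under user-supplied constraints. Implements closed
    full-pattern mining with transaction identifiers (an FP-growth-style itemset
    miner with succinct, anti-monotone, monotone and convertible constraint pushing,
    including mu/alpha data reductions) and closed sequential full-pattern mining by
    prefix projection (with prefix-monotone and regular-expression pruning) for
    order-preserving models. Provides a constraint grammar and classifier,
    annotation-aware mining, discretization with multi-item assignments, a planted
    bicluster synthetic benchmark generator, Jaccard-based match scores, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
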