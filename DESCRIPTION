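Package: olsar
Title: Orthogonal Linear Separation Analysis of Perturbation Response Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes perturbagen response-profile matrices (genes x samples)
    into orthogonal response vectors and per-sample response scores by
    origin-anchored factor analysis: robust rank-based z-scoring against
    vehicle controls, L2-norm "total strength" factorization, Grubbs-gated
    mirror-data augmentation, uncentred principal component extraction to a
    cumulative-contribution threshold, and varimax rotation. Downstream tools
    build factor gene signatures, rank samples by score, test gene-set
    enrichment of factor constituents (Fisher/hypergeometric with
    Benjamini-Hochberg correction and the significant-enrichment ratio), and
    validate factors against held-out data sets by Spearman correlation. A
    synthetic-data generator with planted sparse orthogonal factors supports
    end-to-end testing, and a command-line interface orchestrates the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
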