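Package: metasucc
Title: Metacommunity Analysis of Secondary-Forest Succession
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landscape-scale analysis of woody-plant community assembly
    along a secondary-forest chronosequence. Provides Hill-number
    diversity profiles, exact individual-based rarefaction, sample-based
    accumulation and resampled metacommunity (gamma) diversity with
    quantile confidence limits; abundance-based Jaccard (Ruzicka),
    presence/absence Jaccard, Morisita-Horn and the Chao-Jaccard
    abundance estimator with its unseen-shared-species correction;
    non-metric multidimensional scaling with multiple random starts and
    PCA rotation; Mantel tests, Mantel correlograms and one-factor
    permutational MANOVA; linear, power and exponential succession
    regressions with model selection; landscape occurrence (F1) and
    local-dominance (F5) frequencies with rank-frequency curves and
    between-class turnover; and relative-size-threshold effective
    diversity summaries by maximum-diameter class. A synthetic
    metacommunity generator (successional niche plus species-specific
    dispersal limitation) and a structureless null generator make the
    whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
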