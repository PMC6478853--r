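Package: latphylodiv
Title: Latitudinal Gradients in Community Phylogenetic Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing latitudinal gradients in the phylogenetic
    diversity of plant communities. Grafts community species lists onto a
    dated reference phylogeny (Phylomatic/BLADJ-style placement within
    genera and families), computes mean pairwise distance (mpd) and mean
    nearest taxon distance (mntd) together with their standardized effect
    sizes (SES) under richness-matched randomization nulls, and models the
    SES indices against latitude, vegetation type, biogeographic realm and
    sampling-unit size with linear mixed-effects models fitted by an
    in-package marginal likelihood, ranked by AICc and summarised with
    Akaike weights, marginal/conditional R-squared and Wald tests. A
    synthetic-data module simulates birth-death phylogenies and communities
    with latitude-dependent phylogenetic clustering so that the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    geosphere,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    nlme,
    withr
Config/testthat/edition: 3
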