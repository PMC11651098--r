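Package: metaelo
Title: Elo-Rating of Taxon Competitiveness and Coalescence Prediction in
    Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dispersal-manipulation experiments on
    microbial metacommunities grown in replicate microcosms. Provides a
    multiplayer Elo-rating of genus-level competitiveness driven by
    within-microcosm abundance ranks (with an exponential-decay score
    function and microcosm-order randomisation), the modified Raup-Crick
    beta-diversity null model with Bray-Curtis distances, rarefaction and
    alpha/gamma diversity summaries, carbon-use-efficiency bookkeeping,
    and neutral versus competitiveness predictions of community
    composition after a homogenizing dispersal (coalescence) event,
    including per-genus model tests with Benjamini-Hochberg correction.
    A metacommunity simulator (dispersal-limited colonisation, serial
    1:10 transfer cycles, final equal-volume coalescence) generates fully
    reproducible synthetic experiments for testing the whole pipeline.
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
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
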