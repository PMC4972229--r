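Package: dscomp
Title: Downscaled Complementarity Surrogates for Conservation Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring complementarity value (rarity-weighted
    richness) from coarse-resolution species occurrence data to
    fine-resolution planning cells, and for scoring any such surrogate
    against true fine-scale inventories. Implements rarity-weighted
    richness, a Zonation-style reverse-greedy core-area site ranking,
    statistical downscaling of complementarity via a random-forest
    regression on environmental predictors selected by varimax-rotated
    factor analysis, direct downscaling of range maps, species
    accumulation curves with the Species Accumulation Index (SAI),
    Pearson correlations with Dutilleul's modified t-test for spatial
    autocorrelation, and a synthetic nested-grid landscape generator for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
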