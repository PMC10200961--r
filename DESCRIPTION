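Package: tlflux
Title: Two-Leaf Conductance-Photosynthesis Modelling of Canopy Transpiration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates gross primary production, canopy stomatal conductance
    and transpiration for temperate deciduous forests with a two-leaf model
    chain: a two-leaf light-use-efficiency model for sunlit and shaded leaf
    photosynthesis, a two-leaf Ball-Berry model for canopy conductance, and
    the Penman-Monteith equation for transpiration. Includes FLUXNET-style
    preprocessing (daytime quality control, daily aggregation, uWUE
    transpiration partitioning, temperature-percentile season identification),
    a synthetic flux-tower data generator with known seasonal parameters, an
    SCE-UA global optimizer, and a randomized calibration/validation
    experiment design comparing fixed growing-season against season-specific
    parameterizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
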