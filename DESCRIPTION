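Package: phenoflow
Title: Soil-Water-Modified Thermal Time Simulation of Chickpea and Wheat Flowering
Version: 0.1.0
Authors@R:
    person("Phenoflow", "Developers", email = "phenoflow@example.org",
           role = c("aut", "cre"))
Description: A daily-time-step crop phenology simulator that predicts chickpea
    and wheat flowering dates from cardinal-temperature thermal time modulated
    by photoperiod, vernalisation (wheat) and fractional available soil water
    (FASW) in the 0-60 cm root zone. Includes a layered tipping-bucket soil
    water balance, a synthetic weather generator, a post-flowering frost
    yield-penalty model, and model-agreement statistics (NRMSE and Lin's
    concordance correlation coefficient with McBride categories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
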