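Package: phytoclim
Title: Phytoclimate Risk Assessment with Process-Based Plant Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess climate-change risk for terrestrial vegetation by
    transforming gridded monthly climatologies into phytoclimates: vectors of
    climatic suitability for 14 plant growth forms. A transport-resistance
    plant growth model with a Farquhar-type C3/C4 carbon-uptake ceiling is
    fitted per species from presence/pseudo-absence data by Differential
    Evolution, suitability maps are binarized and filtered by the true skill
    statistic, growth-form suitability surfaces are clustered into
    phytoclimatic zones with Gaussian mixtures, and Euclidean-distance indices
    of local change, novelty and disappearance of phytoclimates are computed
    under future climate scenarios. Includes a monthly bucket soil-moisture
    model with Hargreaves potential evapotranspiration and a synthetic-data
    generator of climatologies and virtual species for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    MASS,
    mclust,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
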