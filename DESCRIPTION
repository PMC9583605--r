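Package: mcpafate
Title: Spatial Degrader Heterogeneity and Pesticide Fate in Unsaturated Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based scenario analysis of how millimeter-scale spatial
    aggregation of microbial pesticide degraders and precipitation regime
    control degradation, persistence and leaching of the phenoxy herbicide
    MCPA in an unsaturated, layered soil column. Provides van
    Genuchten-Mualem soil hydraulics with a mass-conservative variably
    saturated flow solver, log-Gaussian Cox process generation of spatially
    aggregated degrader abundance fields, advection-dispersion-sorption
    transport with Freundlich equilibrium sorption and Monod biodegradation,
    and a scale-transition (spatial moment) decomposition of macroscopic
    degradation rates into mean-field, covariance, variance and higher-order
    contributions. Scenario orchestration reproduces ensembles over four
    degrader heterogeneity levels and two precipitation regimes, with
    depth-resolved residual concentration, detectability, leaching and DT50
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
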