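Package: jgrass
Title: Individual-Based Simulation of Herbicide-Resistance Evolution in
    Seed- and Rhizome-Propagated Perennial Weeds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based model of a perennial grass weed
    (Johnsongrass, Sorghum halepense) that propagates through both seeds and
    rhizomes, under postemergence herbicide selection and tillage in annual
    soybean cropping. Resistance is inherited either through a single dominant
    nuclear gene (ACCase-inhibiting herbicides) or as a quantitative log-normal
    tolerance trait (glyphosate) following an infinitesimal-model inheritance
    rule. The package provides the annual life-cycle engine, scenario presets
    and regional parameter sets, ensemble simulation with replicate-level
    detection of weed-control failure and evolved resistance, a sensitivity
    driver, parameterization fits for Weibull emergence phenology and
    exponential fecundity decline, synthetic-data generators, and a command
    line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
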