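Package: portnox
Title: Baseline Separation and Spatiotemporal Analysis for Port NO/NO2 Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing high-density low-cost NO and NO2 sensor
    networks in port and cargo-terminal environments. Calibrates raw
    electrochemical sensor signals against reference analysers by multiple
    linear regression with temperature and relative-humidity terms,
    validates them with RMSE and coefficient-of-determination metrics,
    separates each concentration series into a time-varying regional
    baseline and a local emission signal by the lowest-percentile method
    (8-hour window anchors smoothed with a thin-plate regression spline),
    and summarises spatiotemporal patterns: diurnal profiles, functional
    zone statistics, NO/NOx oxidation ratios and local-versus-regional
    contribution fractions. Includes a synthetic sensor-network generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
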