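Package: ultraweed
Title: Ultrasonic and Image-Based Detection of Weed Infestation in Cereals
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for site-specific weed management from proximal sensing of
    cereal plots. Converts ultrasonic sensor voltages into plant heights via a
    linear calibration, locates the circular measurement frame in nadir RGB
    photographs with an HSV-threshold / binary-median / circular-Hough chain,
    measures plant coverage inside the region of interest with the excess green
    index, and relates the sensor heights to weed height, density and biomass
    through correlation, multiple regression with backward elimination, and
    canonical discriminant classification of infestation levels. A synthetic
    data module generates plot images, voltage traces and field tables with
    known ground truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, tools, Rcpp, png, jpeg,
    truncnorm, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
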