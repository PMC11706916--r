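Package: cropclass
Title: Classification of Archaeobotanical Samples by Crop-Processing Stage
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying the crop-processing stage represented by
    archaeobotanical samples of free-threshing cereals and pulses. Weed-seed
    counts are converted into six functional-attribute scores (summed square
    roots of within-sample percentages), samples are classified against a
    four-group ethnographic discriminant model of processing products and
    by-products (winnowing by-product, coarse sieve by-product, fine sieve
    by-product, fine sieve product), and a five-group variant re-enters the
    archaeological samples at the discrimination stage to test
    non-crop-processing origins such as dung burning. Grain, rachis and weed
    proportions can be compared with ethnographic proportions on side-by-side
    ternary plots. A synthetic assemblage generator makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
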