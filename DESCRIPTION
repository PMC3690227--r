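Package: pulleyQuant
Title: Automated Quantification of Pulley Histopathology in Trigger Finger
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Color-based analysis of H&E-stained microscopic images of
    flexor tendon A1 pulleys for grading trigger finger severity. Implements
    statistics-transfer color normalization in the logarithmic lalphabeta
    space, three-step Otsu segmentation of normal (pink) versus metaplastic
    (blue/purple) tissue on the hue channel, active double-threshold nuclei
    segmentation with a shape-based rod/round classifier, and two severity
    indices (abnormal tissue area ratio and abnormal nucleus number ratio)
    with midpoint-threshold stage discrimination and group statistics. A
    seeded synthetic slide generator with exact ground truth supports
    validation without access to original specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
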