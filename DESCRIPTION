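Package: laryngoquant
Title: Quantitative Analysis of Laryngoscopy Images for Laryngopharyngeal Reflux
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying laryngopharyngeal reflux
    (LPR) related changes in endoscopic larynx images: autofocus-style sharp
    frame selection from a frame stack (variance, sum-modulus-difference,
    Sobel gradient, Laplacian energy), brightness compensation by luma
    histogram shifting in YCbCr, automatic segmentation of the glottis,
    vocal cords and arytenoid cartilage by thresholding, structure rules and
    a greedy active-contour model with an entropy-difference adaptive
    stopping rule, extraction of 36 hue and gray-level co-occurrence matrix
    texture features, Fisher linear discriminant feature ranking, an SVM
    detector for LPR and a back-propagation neural network for severity
    grading against reflux symptom index bins. Includes a synthetic laryngeal
    phantom generator with pixel-level ground truth so that every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    png
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
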