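Package: graspfusion
Title: Multimodal Grasp-Type Recognition for Myoelectric Prosthesis Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grasp-type recognition from surface electromyography
    (sEMG) fused with eye tracking and egocentric object detections. A
    continuously running convolutional LSTM classifier over rectified,
    standardized sEMG windows acts as both intent detector and grasp
    classifier; gaze-to-contour association identifies the object the user
    aims to grasp; a restricted-argmax fusion rule limits the classifier
    output to the grasp types paired with that object. Includes a
    protocol-faithful synthetic multimodal recording generator (rest-grasp-rest
    sEMG trials, pre-movement target fixations, distractor objects, detection
    noise), four-fold cross-validation drivers, correct-object-identification
    metrics, and nonparametric comparisons (Wilcoxon signed-rank,
    Mann-Whitney) with rank-biserial effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
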