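Package: impaopt
Title: Improved Marine Predators Algorithm for CNN Hyperparameter Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the marine predators algorithm (MPA) and its
    opposition-based-learning improvement (IMPA) as a reusable optimizer for
    bounded mixed-type hyperparameter spaces, together with a transfer-learning
    image-classification harness (frozen backbone feature extraction followed
    by fine-tuning of the last two convolutional blocks), a synthetic two-class
    image generator for desk-scale experiments, and a classification metric
    suite (accuracy, sensitivity, specificity, precision, macro F-score and
    rank-based AUC) with improvement reporting. The optimizer searches the
    eight-dimensional space of learning rate, batch size, three dropout rates
    and three dense-layer widths used to tune a convolutional classifier head.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
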