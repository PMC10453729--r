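Package: mism
Title: Segmentation Evaluation Metrics with Principled Weak-Label Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation of binary medical image segmentation masks with an
    emphasis on weak labels, i.e. images whose ground-truth mask contains no
    foreground at all (control patients). Implements MISm, a composite metric
    that scores ordinary images with the Dice similarity coefficient and
    weak-label images with a weighted specificity, so that every non-empty
    image receives a defined, informative score. Ships the comparator metrics
    (Dice, specificity, false positive rate, accuracy, normalized Matthews
    correlation coefficient), a score-versus-false-positive-ratio sweep for
    studying scoring gradients, a synthetic mask generator covering normal and
    edge-case prediction scenarios, PNG/NIfTI mask readers and writers, batch
    evaluation with CSV/JSON reports, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    RNifti,
    jsonlite,
    ggplot2,
    rlang,
    withr,
    EBImage,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
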