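Package: keypose
Title: Key-Pose Based Human Activity Recognition from 3D Skeleton Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition of human activities (activities of daily living,
    gestures) from sequences of 3D skeleton joints as captured by RGBD
    sensors. Each frame is converted to a position- and build-invariant
    posture feature (joint-to-torso distance vectors normalized by the
    neck-torso distance); per-sequence k-means extracts K key poses whose
    centroids, sorted by first temporal occurrence, form a fixed-length
    activity feature vector classified by a one-vs-one multiclass SVM with
    RBF kernel. Includes the standard evaluation protocols for this task
    (random splits, leave-one-actor-out "new-person", leave-one-sequence-out),
    sagittal-plane mirroring augmentation, per-class precision/recall and
    confusion-matrix reporting, and a synthetic skeleton-activity generator
    so the whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
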