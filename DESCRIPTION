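Package: mitotrack
Title: Multi-Object Cell Tracking for Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tracking-by-detection for time-lapse microscopy of mitotically
    active cell cultures. Links per-frame bounding-box detections into
    persistent cell identities using an unscented Kalman filter over an
    eight-dimensional box state, multi-scale pooled appearance embeddings
    compared by cosine distance, chi-squared Mahalanobis gating, Hungarian
    one-to-one assignment inside an age-prioritised matching cascade, and
    gap-filling of transient missed detections with filter-predicted boxes.
    Includes the Modified Recall and Average IoU evaluation metrics, an
    identity-switch counter, a synthetic cell-motion simulator with division
    events and detector degradation for end-to-end testing, and readers and
    writers for MOT-challenge and YOLO-style detection files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
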