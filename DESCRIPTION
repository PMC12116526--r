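Package: agrifusion
Title: Multimodal Anomaly Detection and Adaptive Resource Allocation for
    Precision Agriculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seedable toolkit for zone-based precision agriculture built
    around a synthetic multi-zone field simulator with known ground truth.
    Provides multimodal sensor fusion mathematics (per-modality encoders and
    shared-space projection, spatial attention, cross-modal scaled
    dot-product attention with residual fusion, recurrent and
    transformer-style temporal aggregation), Mahalanobis/Euclidean anomaly
    scoring with quantile threshold calibration and standard detection
    metrics, a concave multi-objective resource-allocation optimizer
    (yield minus weighted cost and environmental impact, under budget and
    per-zone cap constraints) with an analytic oracle and KKT certificate,
    priority-score proportional allocation with cap-and-renormalize
    redistribution, and a closed-loop feedback controller that adjusts
    allocations and priorities from observed-vs-predicted deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
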