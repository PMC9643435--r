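Package: lymphmotion
Title: Motility Analysis of Lymphocytes in 4D Live Microscopy
Version: 0.1.0
Authors@R:
    person("Lymphmotion", "Developers", email = "lymphmotion@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of lymphocyte motility in time-lapse
    fluorescence microscopy of lymphoid tissue. Provides a synthetic movie
    and track generator with phenotype-specific motion and morphology, cell
    detection and track linking, translation/rotation-invariant movement
    features, ellipse morphology, descriptive motility statistics, dense
    optical flow for the follicular dendritic cell network, four
    "information level" phenotype classifiers (logistic regression and
    1D/2D/3D convolutional networks) with pixel-level AUC evaluation,
    layer-wise relevance propagation, and k-means clustering of tracks into
    directed and undirected movement classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
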