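Package: keyposes
Title: Multiview Human Action Recognition with Radial Silhouette Features
    and a Bag of Key Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes human actions from sequences of binary silhouette
    masks recorded by one or more cameras. Each silhouette contour is reduced
    to a low-dimensional radial feature (equal-angle bins around the contour
    centroid, summarized per bin by the variance, maximum or range of the
    centroid distances, normalized to unit sum). A multiview bag of key poses
    is learned by per-view, per-class K-means clustering; each key pose
    carries a discriminative weight given by its ratio of within-class
    nearest-neighbour matches. Sequences are rewritten as sequences of key
    poses and classified by nearest-neighbour dynamic time warping with a
    relevance-weighted cost, fusing views through the best (lowest-distance)
    view. Includes a deterministic synthetic multiview silhouette generator
    and leave-one-sequence-out / leave-one-actor-out evaluation protocols
    with a median-over-repetitions parameter sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
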