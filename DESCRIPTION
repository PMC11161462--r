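Package: baitbehave
Title: Automatic Fish Behavior Recognition from Bait-Camera Tracks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and classifies fish behavior around a baited
    underwater camera from multi-object-tracking output. Computes
    stimulus-relative trajectory metrics (step lengths, turning angles,
    distance and bearing to bait, squared net displacement, proximity-zone
    occupancy), reduces the metric pool by pairwise-correlation filtering and
    Random-Forest recursive feature elimination, determines the number of
    behavior partitions by gap statistic, elbow and silhouette consensus,
    trains thresholded Random Forest classifiers for the Interested versus
    Uninterested principal behaviors and eight fine-scale behaviors, and
    compares bait types from hourly activity series with Kruskal-Wallis and
    Dunn post-hoc tests. Ships a seeded correlated-random-walk generator of
    labeled fish tracks with a tracker-imperfection model (dropouts, track
    splits, bounding-box jitter, confidence noise, clutter) so the whole
    chain is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    cluster,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
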