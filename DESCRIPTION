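Package: DepthTAL
Title: Temporal Action Localization for In-Home Depth and Skeleton Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recognizes and temporally localizes daily activities (walking,
    reaching, hand manipulation) in untrimmed depth-camera recordings and
    19-joint skeleton streams of the kind produced by ambient in-home
    monitoring sensors. Provides the on-disk logger formats (16-bit depth
    PNG frames, compressed cache blocks, skeleton streams, label tracks),
    a synthetic home-session generator with per-frame ground truth, HON4D
    4D-surface-normal descriptors with a linear clip classifier,
    anchor-based temporal proposal machinery, three small detector
    networks (a per-frame convolutional-de-convolutional scorer, an
    anchor-based segment detector on depth, and a skeleton co-occurrence
    detector), majority-vote label fusion, and per-frame / per-action
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
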