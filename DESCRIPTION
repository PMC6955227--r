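Package: froglet
Title: Automated Kinematic Analysis of Froglet Swimming Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hindlimb function of post-metamorphic Xenopus
    laevis froglets from dorsal-view swimming videos. The pipeline segments
    and tracks the animal, orients the body head-up, locates the four limb
    endpoints from the morphological skeleton, and summarizes each video into
    four kinematic features (hindfoot synchronization, stroke symmetry, and
    the angular range of motion of each hindfoot) together with a 180 x 180
    joint-angle histogram. A suite of classical classifiers with repeated
    stratified cross-validation grades videos into three spinal-cord damage
    categories (uninjured, hemisected, transected). A fully parameterized
    synthetic-video generator renders articulated swimming froglets with
    per-frame ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    e1071,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
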