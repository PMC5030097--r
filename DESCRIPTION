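Package: coilTrack
Title: Generative Posture Tracking and Turn Analytics for Coiled Nematodes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resolves self-occluding (coiled) body postures of crawling
    nematodes from binary movie frames by inverting a generative model: body
    shapes are represented as points in a low-dimensional eigenworm posture
    space, rendered back into binary images, and matched to movie frames with
    a two-metric image error function minimized by multi-restart pattern
    search. Includes the classic thinning tracker for uncrossed frames, a
    dynamic-programming sequence filter with head/tail resolution, behavioral
    analytics (omega/delta turn detection and classification, escape-response
    segmentation, reorientation through coils, turn-rate adaptation, event
    mutual information), and a synthetic worm-movie generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, EBImage, jsonlite, png, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, BehavioralResearch
NeedsCompilation: yes
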