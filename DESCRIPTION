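Package: PalateSeg
Title: Multiview 3D Semantic Segmentation of Maxillary Scans and Rugae-Anchored Tooth Motion Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semantic segmentation of textured 3D maxillary scans
    and for measuring orthodontic tooth movement. Labeled triangle meshes are
    projected into 2D images from randomized hemisphere camera poses with a
    software rasterizer, segmented with a SegNet-style encoder-decoder
    network with optional channel and spatial attention, and the per-pixel
    predictions are baked back onto mesh vertices by multiview voting to
    yield a per-vertex 3D segmentation. Per-tooth rigid motion between pre-
    and post-treatment scans is estimated by two-stage iterative closest
    point registration anchored on the palatal rugae, and decomposed into
    three rotations and three translations. A synthetic dental-arch
    generator provides labeled test data with known ground-truth motion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Rcpp, png, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
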