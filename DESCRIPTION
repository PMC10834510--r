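Package: cagecodec
Title: Dual-Stream Bit-Plane Compression and Keypoint Evaluation for
    Home-Cage Depth Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compressing and evaluating 16-bit depth video from
    top-down home-cage monitoring of laboratory mice. Each 16-bit depth
    frame is split into its most-significant and least-significant byte
    planes, which are encoded as two separate 8-bit streams: the slowly
    varying MSB plane losslessly, the rapidly varying LSB plane at a
    configurable quality rung. Recordings can be decoded back to depth,
    verified bit-for-bit, and scored with MSE/PSNR and compression-ratio
    reports. The package also implements the keypoint-evaluation
    machinery used to validate pose tracking on depth video:
    RGB-to-depth annotation transfer, train/validation/test
    partitioning, inter-annotator sigma estimation, and object keypoint
    similarity (OKS) scoring with per-coat-color aggregation, exercised
    end-to-end on a synthetic depth-scene generator with ground-truth
    keypoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
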