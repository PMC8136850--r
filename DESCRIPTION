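Package: fioseg
Title: Fuzzy Intensification Contrast Enhancement and Two-Class
    Segmentation Evaluation for Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contrast enhancement of B-mode breast ultrasound images with the
    fuzzy intensification operator (min-max fuzzification, membership
    intensification, de-fuzzification), pluggable two-class tumor/normal-tissue
    segmentation backends runnable in batch or one-by-one inference mode, and
    the standard semantic-segmentation evaluation suite: global accuracy,
    per-class and mean Jaccard index (IoU), pixelwise F1 (Dice) and
    distance-tolerant boundary-F1 score, with image-set and cross-table
    averaging in the layout used by published breast-ultrasound segmentation
    benchmarks. A seeded speckle-phantom generator produces paired
    ultrasound-like images and ground-truth masks so the whole pipeline runs
    without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
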