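Package: adseg
Title: Brain MRI Slice Segmentation and Classification with Swarm-Optimised
    Otsu Thresholding, Texture Fusion and Deep Belief Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for region-of-interest analysis of 2-D grayscale brain
    MRI slices. Segments images by Otsu thresholding whose optimal threshold
    is located with the Tunicate Swarm Algorithm, extracts local binary
    pattern (LBP) and local directional pattern variance (LDPv) texture
    descriptors from the segmented region and fuses them at feature level,
    and classifies the fused descriptors with a from-scratch deep belief
    network (stacked restricted Boltzmann machines pretrained by contrastive
    divergence and fine-tuned by backpropagation). Includes Jaccard, Dice,
    pixel-accuracy, sensitivity and specificity evaluation metrics, a
    seedable synthetic phantom generator with known ground-truth masks for
    desk-scale validation, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
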