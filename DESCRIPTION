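Package: vedicnn
Title: Bit-Accurate Vedic Arithmetic Emulation and Denoising-CNN Segmentation
    of Breast-Ultrasound Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software emulation of hardware-oriented arithmetic units built from
    Vedic multiplication sutras - the vertical-crosswise (Urdhva Tiryagbhyam)
    multiplier, the Nikhilam/Anurupyena base-complement multiplier, the hybrid
    CUTIN multiplier, and a carry-save adder with clarified sum/carry generation
    logic (CSCGL) - together with IEEE-754 floating-point multiplication and
    addition emulated on top of them. Convolution, batch-normalisation and ReLU
    layers can route every multiply-accumulate through the emulated datapath, so
    a desk-scale denoising CNN (DnCNN) for breast-lesion segmentation can be
    trained in host arithmetic and run through the bit-accurate backend. Includes
    a Pelican Optimization Algorithm for hyperparameter tuning, a seeded
    generator of speckle-noised ultrasound-like lesion phantoms with ground-truth
    masks, segmentation and image-quality metrics (Dice, IoU, PSNR, SSIM), a
    maximum-margin lesion classifier, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
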